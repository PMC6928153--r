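# Fast-math is safe here: the RK4 kernel evaluates bounded trigonometric
# sums (the phase velocities are bounded by |omega| + K), and the 4-ulp
# vectorized sin/cos is far below the O(dt^4) integration error.  The
# finiteness guard lives in guard.cpp, compiled without fast-math.
PKG_CXXFLAGS = -O3 -ffast-math

guard.o: PKG_CXXFLAGS = -O3
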