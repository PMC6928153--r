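// Finiteness guard, kept in its own translation unit so it is compiled
// without fast-math (which would let the compiler assume no NaN/Inf and
// fold the checks away).
#include <cmath>

extern "C" bool kuranet_all_finite(const double *x, int n) {
    for (int i = 0; i < n; ++i)
        if (!std::isfinite(x[i])) return false;
    return true;
}
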