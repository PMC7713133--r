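/* Pair-count kernel for approximate entropy: Phi^m(r) with Chebyshev
 * distances and self-matches included.  O(N^2 m); called through .C. */
#include <R.h>
#include <math.h>

void apen_phi_kernel(double *s, int *n, int *m, double *r, double *phi)
{
    int N = *n, M = *m;
    int Nm = N - (M - 1);
    double sum = 0.0, rr = *r;
    if (Nm < 1) { *phi = NA_REAL; return; }
    for (int i = 0; i < Nm; i++) {
        int cnt = 0;
        for (int j = 0; j < Nm; j++) {
            int hit = 1;
            for (int k = 0; k < M; k++) {
                double d = fabs(s[i + k] - s[j + k]);
                if (d >= rr) { hit = 0; break; }
            }
            cnt += hit;
        }
        sum += log((double) cnt / (double) Nm);
    }
    *phi = sum / (double) Nm;
}
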