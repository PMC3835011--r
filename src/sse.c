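/* Penalized sum-of-squares objective for the four-parameter
 * retinal-function model.  Hot loop of the multi-start / bootstrap
 * fitting; must stay numerically identical to the R forward model
 * (erg_model composed over the records). */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

SEXP C_sse(SEXP theta_, SEXP flow_, SEXP iop_, SEXP erg_,
           SEXP lo_, SEXP hi_)
{
    double *th = REAL(theta_), *lo = REAL(lo_), *hi = REAL(hi_);
    double t4[4], pen = 0.0;
    for (int j = 0; j < 4; j++) {
        double v = th[j];
        double c = v < lo[j] ? lo[j] : (v > hi[j] ? hi[j] : v);
        pen += (v - c) * (v - c);
        t4[j] = c;
    }
    double a = t4[0], b = t4[1], t = t4[2], m = t4[3];
    double E = exp(100.0 * b);
    int n = LENGTH(flow_);
    double *f = REAL(flow_), *io = REAL(iop_), *e = REAL(erg_);
    double sse = 0.0;
    for (int i = 0; i < n; i++) {
        double cons = f[i] * (a * exp(b * f[i]) + (1.0 - a * E));
        double iopm = io[i] > t ? m * (io[i] - t) : 0.0;
        double pred = cons + iopm;
        if (pred < 0.0) pred = 0.0;
        double r = e[i] - pred;
        sse += r * r;
    }
    return ScalarReal(sse + 1e6 * pen);
}
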