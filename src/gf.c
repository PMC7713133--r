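/* Gyorgyi-Field three-variable BZ model: right-hand side, analytic
 * Jacobian, and the 12-dimensional tangent-space extension used for
 * Lyapunov spectra.  Compiled-model interface for deSolve.
 *
 * Parameter vector (length 19), order fixed and shared with R/gf_model.R:
 *   k1..k7, A, H, M, C, alpha, beta, kf, T0, X0, Y0, Z0, V0
 */
#include <R.h>
#include <math.h>

static double parms[19];
#define P_k1    parms[0]
#define P_k2    parms[1]
#define P_k3    parms[2]
#define P_k4    parms[3]
#define P_k5    parms[4]
#define P_k6    parms[5]
#define P_k7    parms[6]
#define P_A     parms[7]
#define P_H     parms[8]
#define P_M     parms[9]
#define P_C     parms[10]
#define P_alpha parms[11]
#define P_beta  parms[12]
#define P_kf    parms[13]
#define P_T0    parms[14]
#define P_X0    parms[15]
#define P_Y0    parms[16]
#define P_Z0    parms[17]
#define P_V0    parms[18]

void gf_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

/* shared evaluation of the vector field; x clamped at 0 for the x^0.5
 * terms to absorb solver round-off (negative overshoot of O(eps)) */
static void gf_field(const double *y, double *f)
{
    double x = y[0], z = y[1], v = y[2];
    double xc = x > 0.0 ? x : 0.0;
    double xs = sqrt(xc);
    double b  = P_k2 * P_A * P_H * P_H;
    double den = P_k1 * P_H * P_X0 * x + b + P_kf;
    double w  = den > 0.0
        ? P_alpha * P_k6 * P_Z0 * P_V0 * z * v / den : 0.0; /* = Y0*ytilde */
    double c4 = 0.5 * P_k4 * sqrt(P_A) * pow(P_H, 1.5) / sqrt(P_X0);
    double d4 = P_k4 * sqrt(P_A) * pow(P_H, 1.5) * sqrt(P_X0);

    f[0] = P_T0 * (-P_k1 * P_H * x * w + (b / P_X0) * w
                   - 2.0 * P_k3 * P_X0 * x * x
                   + c4 * (P_C - P_Z0 * z) * xs
                   - 0.5 * P_k5 * P_Z0 * x * z - P_kf * x);
    f[1] = P_T0 * (d4 * (P_C / P_Z0 - z) * xs - P_k5 * P_X0 * x * z
                   - P_alpha * P_k6 * P_V0 * z * v
                   - P_beta * P_k7 * P_M * z - P_kf * z);
    f[2] = P_T0 * (2.0 * P_k1 * P_H * (P_X0 / P_V0) * x * w
                   + (b / P_V0) * w + P_k3 * P_X0 * P_X0 / P_V0 * x * x
                   - P_alpha * P_k6 * P_Z0 * z * v - P_kf * v);
}

/* analytic Jacobian, column-major 3x3 in J */
static void gf_jacmat(const double *y, double *J)
{
    double x = y[0], z = y[1], v = y[2];
    double xc = x > 0.0 ? x : 1e-300; /* x>0 required; guarded in R */
    double xs = sqrt(xc);
    double b  = P_k2 * P_A * P_H * P_H;
    double a  = P_k1 * P_H * P_X0;
    double den = a * x + b + P_kf;
    double G  = P_alpha * P_k6 * P_Z0 * P_V0;
    double w  = G * z * v / den;
    double wx = -w * a / den;
    double wz = G * v / den;
    double wv = G * z / den;
    double c4 = 0.5 * P_k4 * sqrt(P_A) * pow(P_H, 1.5) / sqrt(P_X0);
    double d4 = P_k4 * sqrt(P_A) * pow(P_H, 1.5) * sqrt(P_X0);
    double e1 = 2.0 * P_k1 * P_H * P_X0 / P_V0;
    double e2 = b / P_V0;
    double e3 = P_k3 * P_X0 * P_X0 / P_V0;
    double g1 = -P_k1 * P_H * x + b / P_X0; /* coefficient of w in f1 */

    /* column 1: d/dx */
    J[0] = P_T0 * (-P_k1 * P_H * (w + x * wx) + (b / P_X0) * wx
                   - 4.0 * P_k3 * P_X0 * x
                   + 0.5 * c4 * (P_C - P_Z0 * z) / xs
                   - 0.5 * P_k5 * P_Z0 * z - P_kf);
    J[1] = P_T0 * (0.5 * d4 * (P_C / P_Z0 - z) / xs - P_k5 * P_X0 * z);
    J[2] = P_T0 * (e1 * (w + x * wx) + e2 * wx + 2.0 * e3 * x);
    /* column 2: d/dz */
    J[3] = P_T0 * (g1 * wz - c4 * P_Z0 * xs - 0.5 * P_k5 * P_Z0 * x);
    J[4] = P_T0 * (-d4 * xs - P_k5 * P_X0 * x - P_alpha * P_k6 * P_V0 * v
                   - P_beta * P_k7 * P_M - P_kf);
    J[5] = P_T0 * ((e1 * x + e2) * wz - P_alpha * P_k6 * P_Z0 * v);
    /* column 3: d/dv */
    J[6] = P_T0 * (g1 * wv);
    J[7] = P_T0 * (-P_alpha * P_k6 * P_V0 * z);
    J[8] = P_T0 * ((e1 * x + e2) * wv - P_alpha * P_k6 * P_Z0 * z - P_kf);
}

void gf_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    gf_field(y, ydot);
}

void gf_jac(int *neq, double *t, double *y, int *ml, int *mu,
            double *pd, int *nrowpd, double *yout, int *ip)
{
    double J[9];
    int i, j;
    gf_jacmat(y, J);
    for (j = 0; j < 3; j++)
        for (i = 0; i < 3; i++)
            pd[j * (*nrowpd) + i] = J[j * 3 + i];
}

/* state + 3 tangent vectors (columns), du/dtau = J(state) u */
void gf_tderivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double J[9];
    int c, i, k;
    gf_field(y, ydot);
    gf_jacmat(y, J);
    for (c = 0; c < 3; c++) {
        const double *u = y + 3 + 3 * c;
        double *du = ydot + 3 + 3 * c;
        for (i = 0; i < 3; i++) {
            double s = 0.0;
            for (k = 0; k < 3; k++)
                s += J[k * 3 + i] * u[k];
            du[i] = s;
        }
    }
}
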