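/* Closed-loop CO2 chemoreflex model: alveolar and tissue CO2 mass
 * balances, first-order brain-tissue (effect-site) PCO2, and the
 * hinge-law ventilation feedback. Compiled right-hand sides for
 * deSolve::lsoda in three driving modes:
 *
 *   co2_closed  - closed loop under a dynamic end-tidal forcing
 *                 controller (PI control of inspired PCO2 toward a
 *                 stepped end-tidal target); states (Pa, Pv, Pbr, z)
 *                 where z is the controller integral.
 *   co2_driven  - open forcing: inspired PCO2 prescribed as a deSolve
 *                 forcing function; states (Pa, Pv, Pbr).
 *   co2_clamped - arterial PCO2 prescribed directly (idealized
 *                 end-tidal clamp); states (Pv, Pbr).
 *
 * Units: pressures mmHg, volumes L, ventilation/cardiac output L/min,
 * time min. Tissue equation implemented as Q*(Pa - Pv) + lam2*VCO2 so
 * that venous exceeds arterial PCO2 at steady state.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 24

static double p[N_PARMS];

#define VALV   p[0]
#define VD     p[1]
#define VTS    p[2]
#define QDOT   p[3]
#define LAM1   p[4]
#define LAM2   p[5]
#define VCO2   p[6]
#define TAU    p[7]
#define DELTA  p[8]
#define B0     p[9]
#define SLOPE  p[10]
#define VRT    p[11]
#define KP     p[12]
#define KI     p[13]
#define PIMAX  p[14]
#define RESTD  p[15]
#define STEPD  p[16]
#define NSTEP  p[17]
#define RESTPET p[18]
#define TAUT   p[19]
/* p[20..23]: end-tidal target increments above resting PETCO2 */

void co2_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double forc[1];

void co2_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* overflow-safe softplus hinge: delta * log(1 + exp(x/delta)) */
static double hingef(double x, double d)
{
    double z = x / d;
    if (z > 30.0) return x;
    if (z < -30.0) return d * exp(z);
    return d * log1p(exp(z));
}

static void core(double pa, double pv, double pbr, double pico2,
                 double *dpa, double *dpv, double *dpbr, double *ve_out)
{
    double ve = B0 + SLOPE * hingef(pbr - VRT, DELTA);
    double valv_vent = ve - VD;           /* alveolar ventilation */
    if (valv_vent < 0.0) valv_vent = 0.0; /* below dead space: no gas exchange */
    *dpa  = (valv_vent * (pico2 - pa) + LAM1 * QDOT * (pv - pa)) / VALV;
    *dpv  = (QDOT * (pa - pv) + LAM2 * VCO2) / VTS;
    *dpbr = (pa - pbr) / TAU;
    *ve_out = ve;
}

void co2_driven(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double ve;
    core(y[0], y[1], y[2], forc[0], &ydot[0], &ydot[1], &ydot[2], &ve);
    if (*ip >= 2) {
        yout[0] = ve;
        yout[1] = forc[0];
    }
}

void co2_closed(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double pico2 = 0.0, dz = 0.0, ve;
    double tt = *t;

    if (tt >= RESTD && NSTEP >= 1.0) {
        int k = (int) floor((tt - RESTD) / STEPD);
        int ns = (int) NSTEP;
        if (k >= ns) k = ns - 1;
        if (k < 0) k = 0;
        /* commanded target: protocol step passed through a short
         * first-order lag (time constant TAUT) so the inspired-gas
         * command stays continuous, as a gas-mixing controller's
         * output does; closed form across the piecewise-constant
         * step sequence */
        double lagged = RESTPET;
        for (int i = 0; i < k; i++) {
            double ti = RESTPET + p[20 + i];
            lagged = ti + (lagged - ti) * exp(-STEPD / TAUT);
        }
        double tk = RESTPET + p[20 + k];
        double target = tk + (lagged - tk) * exp(-(tt - RESTD - k * STEPD) / TAUT);
        double e = target - y[0];
        double u = KP * e + KI * y[3];
        pico2 = u;
        dz = e;
        if (u < 0.0) {            /* inspired CO2 cannot go negative */
            pico2 = 0.0;
            if (e < 0.0) dz = 0.0; /* anti-windup */
        } else if (u > PIMAX) {
            pico2 = PIMAX;
            if (e > 0.0) dz = 0.0;
        }
    }
    core(y[0], y[1], y[2], pico2, &ydot[0], &ydot[1], &ydot[2], &ve);
    ydot[3] = dz;
    if (*ip >= 2) {
        yout[0] = ve;
        yout[1] = pico2;
    }
}

void co2_clamped(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    /* y = (Pv, Pbr); arterial PCO2 prescribed by the forcing */
    double pa = forc[0];
    double ve = B0 + SLOPE * hingef(y[1] - VRT, DELTA);
    ydot[0] = (QDOT * (pa - y[0]) + LAM2 * VCO2) / VTS;
    ydot[1] = (pa - y[1]) / TAU;
    if (*ip >= 2) {
        yout[0] = ve;
        yout[1] = pa;
    }
}

void R_init_hcvr(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
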