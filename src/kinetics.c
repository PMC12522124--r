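/* Three-compartment saturating adsorption/desorption kinetics.
 *
 * State y = (c_o, c_m, c_i): polymer concentration in the outer solution,
 * the membrane, and the inner vesicle volume (common mass-per-volume units).
 * Adsorption acts with the same rate constant k_a on both membrane faces and
 * is blocked by the saturation factor S = 1 - c_m/c_sat; the total desorption
 * rate k_d is split equally between the two faces.  Fluxes are expressed per
 * membrane volume, hence the phi_mem/phi_in and phi_mem/phi_out prefactors on
 * the aqueous compartments; the phi-weighted total is conserved exactly.
 *
 * Compiled-model interface for deSolve (initfunc = "luvtrans_init",
 * func = "luvtrans_derivs", dllname = "luvtrans").
 */
#include <R.h>
#include <math.h>

static double parms[6];
#define KA      parms[0]
#define KD      parms[1]
#define CSAT    parms[2]
#define PHI_OUT parms[3]
#define PHI_MEM parms[4]
#define PHI_IN  parms[5]

void luvtrans_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void luvtrans_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double c_o = y[0], c_m = y[1], c_i = y[2];
    double S = (isfinite(CSAT) && CSAT > 0.0) ? (1.0 - c_m / CSAT) : 1.0;
    double dm = KA * (c_o + c_i) * S - KD * c_m;

    ydot[1] = dm;
    ydot[0] = (PHI_OUT > 0.0)
        ? (PHI_MEM / PHI_OUT) * (0.5 * KD * c_m - KA * c_o * S) : 0.0;
    ydot[2] = (PHI_IN > 0.0)
        ? (PHI_MEM / PHI_IN) * (0.5 * KD * c_m - KA * c_i * S) : 0.0;
}
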