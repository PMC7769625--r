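/* Right-hand sides of the expanded cerebellar stellate cell model for
 * deSolve's compiled-model interface.
 *
 * Full system state (8): V, h, n, nA, hA, hT, mHVA, Ca
 * Fast subsystem state (6): V, h, n, nA, hT, mHVA  (hA, Ca frozen as parms)
 *
 * The parameter vector layout must match .csc_param_vector() on the R side.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 55

static double parms[N_PARMS];

/* named accessors into parms (0-based) */
#define P_C        parms[0]
#define P_IAPP     parms[1]
#define P_GNA      parms[2]
#define P_GK       parms[3]
#define P_GL       parms[4]
#define P_GA       parms[5]
#define P_GT       parms[6]
#define P_GHVA     parms[7]
#define P_GKCA     parms[8]
#define P_ENA      parms[9]
#define P_EK       parms[10]
#define P_EL       parms[11]
#define P_ECA      parms[12]
#define P_VM       parms[13]
#define P_SM       parms[14]
#define P_VH       parms[15]
#define P_SH       parms[16]
#define P_VN       parms[17]
#define P_SN       parms[18]
#define P_VNA      parms[19]
#define P_SNA      parms[20]
#define P_TAUNA    parms[21]
#define P_VHA      parms[22]
#define P_SHA      parms[23]
#define P_TAUHA    parms[24]
#define P_VMT      parms[25]
#define P_SMT      parms[26]
#define P_VHT      parms[27]
#define P_SHT      parms[28]
#define P_TAUHT    parms[29]
#define P_VMHVA    parms[30]
#define P_SMHVA    parms[31]
#define P_TAUMHVA  parms[32]
#define P_Y0       parms[33]
#define P_A        parms[34]
#define P_W        parms[35]
#define P_VC       parms[36]
#define P_KCA      parms[37]
#define P_ALPHA    parms[38]
#define P_K        parms[39]
#define P_EPS      parms[40]
#define P_PROT     parms[41]
#define P_IBIAS    parms[42]
#define P_ITEST    parms[43]
#define P_TSTEP    parms[44]
#define P_GINH     parms[45]
#define P_GEXC     parms[46]
#define P_EINH     parms[47]
#define P_EEXC     parms[48]
#define P_TAUINH   parms[49]
#define P_TAUEXC   parms[50]
#define P_ONSINH   parms[51]
#define P_ONSEXC   parms[52]
#define P_FROZ_HA  parms[53]
#define P_FROZ_CA  parms[54]

void csc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double xinf(double V, double vx, double sx)
{
    return 1.0 / (1.0 + exp(-(V - vx) / sx));
}

static double tau_h_of(double V)
{
    double d = V - P_VC;
    return P_Y0 + (2.0 * P_A / M_PI) * P_W / (4.0 * d * d + P_W * P_W);
}

static double tau_n_of(double V)
{
    return 6.0 / (1.0 + exp((V + 23.0) / 15.0));
}

static double alpha_fun(double t, double tau, double onset)
{
    double s;
    if (t < onset) return 0.0;
    s = (t - onset) / tau;
    return s * exp(1.0 - s);
}

/* applied current (density) at time t, may include synaptic term via V */
static double applied_current(double t, double V)
{
    int kind = (int) P_PROT;
    double I = P_IAPP;
    if (kind == 1) {                       /* current step */
        I = (t < P_TSTEP) ? P_IBIAS : P_ITEST;
    } else if (kind == 2) {                /* inhibitory/excitatory pair */
        double gi = P_GINH * alpha_fun(t, P_TAUINH, P_ONSINH);
        double ge = P_GEXC * alpha_fun(t, P_TAUEXC, P_ONSEXC);
        I -= gi * (V - P_EINH) + ge * (V - P_EEXC);
    }
    return I;
}

/* shared current computation; gates supplied by caller */
static void currents(double V, double h, double n, double nA, double hA,
                     double hT, double mHVA, double Ca, double *I)
{
    double minf  = xinf(V, P_VM, P_SM);
    double mTinf = xinf(V, P_VMT, P_SMT);
    double ca5, hill;
    I[0] = P_GNA * minf * minf * minf * h * (V - P_ENA); /* INa  */
    I[1] = P_GK * n * n * n * n * (V - P_EK);            /* IK   */
    I[2] = P_GL * (V - P_EL);                            /* IL   */
    I[3] = P_GA * nA * hA * (V - P_EK);                  /* IA   */
    I[4] = P_GT * mTinf * hT * (V - P_ECA);              /* IT   */
    I[5] = P_GHVA * mHVA * (V - P_ECA);                  /* IHVA */
    ca5  = pow(Ca, 5.0);
    hill = ca5 / (pow(P_KCA, 5.0) + ca5);
    I[6] = P_GKCA * hill * (V - P_EK);                   /* IKCa */
}

void csc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double V = y[0], h = y[1], n = y[2], nA = y[3], hA = y[4],
           hT = y[5], mHVA = y[6], Ca = y[7];
    double I[7];

    currents(V, h, n, nA, hA, hT, mHVA, Ca, I);
    ydot[0] = (applied_current(*t, V)
               - I[0] - I[1] - I[2] - I[3] - I[4] - I[5] - I[6]) / P_C;
    ydot[1] = (xinf(V, P_VH, P_SH) - h) / tau_h_of(V);
    ydot[2] = (xinf(V, P_VN, P_SN) - n) / tau_n_of(V);
    ydot[3] = (xinf(V, P_VNA, P_SNA) - nA) / P_TAUNA;
    ydot[4] = (xinf(V, P_VHA, P_SHA) - hA) / P_TAUHA;
    ydot[5] = (xinf(V, P_VHT, P_SHT) - hT) / P_TAUHT;
    ydot[6] = (xinf(V, P_VMHVA, P_SMHVA) - mHVA) / P_TAUMHVA;
    ydot[7] = -P_EPS * (P_ALPHA * (I[4] + I[5]) + P_K * Ca);
}

/* fast subsystem: hA and Ca frozen at P_FROZ_HA / P_FROZ_CA */
void csc_fast_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double V = y[0], h = y[1], n = y[2], nA = y[3],
           hT = y[4], mHVA = y[5];
    double I[7];

    currents(V, h, n, nA, P_FROZ_HA, hT, mHVA, P_FROZ_CA, I);
    ydot[0] = (applied_current(*t, V)
               - I[0] - I[1] - I[2] - I[3] - I[4] - I[5] - I[6]) / P_C;
    ydot[1] = (xinf(V, P_VH, P_SH) - h) / tau_h_of(V);
    ydot[2] = (xinf(V, P_VN, P_SN) - n) / tau_n_of(V);
    ydot[3] = (xinf(V, P_VNA, P_SNA) - nA) / P_TAUNA;
    ydot[4] = (xinf(V, P_VHT, P_SHT) - hT) / P_TAUHT;
    ydot[5] = (xinf(V, P_VMHVA, P_SMHVA) - mHVA) / P_TAUMHVA;
}
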