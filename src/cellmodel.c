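/* Right-hand sides for the reduced spontaneously beating hiPSC-CM model
 * ("hpcm1") and its coupling to the channel-expression regulation ODEs,
 * in the deSolve compiled-model convention.
 *
 * Units: time ms, voltage mV, concentrations mM, currents pA/pF.
 *
 * State layout:
 *   y[0..8] = V, mNa, hNa, d, f, xr, yf, c, csr      (cell states)
 *   mode 1 (coupled two-ODE):      y[9] = m, y[10] = n
 *   mode 2 (coupled bounded scalar): y[9] = n
 *
 * Parameter vector layout must match .hpcm_parms_vector() on the R side.
 */
#include <R.h>
#include <math.h>

#define NPARMS 53

static double parms[NPARMS];

void hpcm_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* indices into parms */
enum {
    P_GNA, P_GNAL, P_GCAL, P_GKR, P_GK1, P_GF, P_GBNA,
    P_ENA, P_EK, P_EF, P_ECAL, P_KFCA,
    P_TAUM, P_TAUHA, P_TAUHB, P_TAUD, P_TAUF, P_TAUXRA, P_TAUXRD, P_TAUY,
    P_JCONV, P_VBG, P_VPUMP, P_KPUMP, P_VUP, P_KUP,
    P_GREL, P_KTRIG, P_KSAT, P_VLEAK, P_VSINK, P_VRATIO, P_BETAC,
    P_SCAL, P_SNA, P_SF, P_SKR, P_SK1, P_SSERCA, P_SNCX, P_SBNA, P_SBCA,
    P_BDRUG, P_MODE, P_NFIX,
    P_TAUMREG, P_TAUNTRAF, P_TAUSCAL, P_CSTAR,
    P_NMINUS, P_NPLUS, P_EPSN, P_EPSC
};

static double sigmoid_gate(double a, double b, double eps)
{
    return 0.5 * (1.0 + tanh((a - b) / eps));
}

void hpcm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double V = y[0], mNa = y[1], hNa = y[2], d = y[3], f = y[4];
    double xr = y[5], yf = y[6], c = y[7], csr = y[8];
    int mode = (int) parms[P_MODE];
    double nrel;

    if (c < 1e-9) c = 1e-9;

    if (mode == 1)      nrel = y[10];
    else if (mode == 2) nrel = y[9];
    else                nrel = parms[P_NFIX];

    double nb = nrel * parms[P_BDRUG];

    double INa  = parms[P_SNA] * parms[P_GNA] * mNa * mNa * mNa * hNa *
                  (V - parms[P_ENA]);
    double INaL = parms[P_SNA] * parms[P_GNAL] *
                  (1.0 / (1.0 + exp(-(V + 57.0) / 5.0))) * (V - parms[P_ENA]);
    double kf2  = parms[P_KFCA] * parms[P_KFCA];
    double fca  = kf2 / (kf2 + c * c);
    double ICaL = nb * parms[P_SCAL] * parms[P_GCAL] * d * f * fca *
                  (V - parms[P_ECAL]);
    double rKr  = 1.0 / (1.0 + exp((V - 10.0) / 15.0));
    double IKr  = parms[P_SKR] * parms[P_GKR] * xr * rKr * (V - parms[P_EK]);
    double IK1  = parms[P_SK1] * parms[P_GK1] * (V - parms[P_EK]) /
                  (1.0 + exp((V + 48.0) / 12.0));
    double If   = parms[P_SF] * parms[P_GF] * yf * (V - parms[P_EF]);
    double IbNa = parms[P_SBNA] * parms[P_GBNA] * (V - parms[P_ENA]);

    ydot[0] = -(INa + INaL + ICaL + IKr + IK1 + If + IbNa);

    double minf = 1.0 / (1.0 + exp(-(V + 36.0) / 5.5));
    double hinf = 1.0 / (1.0 + exp((V + 62.0) / 5.5));
    double tauh = parms[P_TAUHA] + parms[P_TAUHB] /
                  (1.0 + exp((V + 50.0) / 6.0));
    double dinf = 1.0 / (1.0 + exp(-(V + 2.0) / 5.5));
    double finf = 1.0 / (1.0 + exp((V + 26.0) / 5.0));
    double xinf = 1.0 / (1.0 + exp(-(V + 20.0) / 8.0));
    double tauxr = parms[P_TAUXRA] + parms[P_TAUXRD] /
                   (1.0 + exp((V + 45.0) / 8.0));
    double yinf = 1.0 / (1.0 + exp((V + 78.0) / 7.0));

    ydot[1] = (minf - mNa) / parms[P_TAUM];
    ydot[2] = (hinf - hNa) / tauh;
    ydot[3] = (dinf - d) / parms[P_TAUD];
    ydot[4] = (finf - f) / parms[P_TAUF];
    ydot[5] = (xinf - xr) / tauxr;
    ydot[6] = (yinf - yf) / parms[P_TAUY];

    double JCaL = -parms[P_JCONV] * ICaL;
    if (JCaL < 0.0) JCaL = 0.0;
    double Jbg   = parms[P_SBCA] * parms[P_VBG];
    double Jpump = parms[P_SNCX] * parms[P_VPUMP] * c * c /
                   (c * c + parms[P_KPUMP] * parms[P_KPUMP]);
    double Jup   = parms[P_SSERCA] * parms[P_VUP] * c * c /
                   (c * c + parms[P_KUP] * parms[P_KUP]);
    double Jrel  = parms[P_GREL] * (JCaL / (JCaL + parms[P_KTRIG])) *
                   (csr / (csr + parms[P_KSAT]));
    double Jleak = parms[P_VLEAK] * (csr - c);
    double Jsink = parms[P_VSINK] * csr;

    ydot[7] = parms[P_BETAC] * (JCaL + Jbg + Jrel + Jleak - Jup - Jpump);
    ydot[8] = parms[P_VRATIO] * (Jup - Jrel - Jleak - Jsink);

    if (mode == 1) {
        /* tau_m dm/dt = c* - c ; tau_n dn/dt = m - n */
        ydot[9]  = (parms[P_CSTAR] - c) / parms[P_TAUMREG];
        ydot[10] = (y[9] - y[10]) / parms[P_TAUNTRAF];
    } else if (mode == 2) {
        /* tau dn/dt = (c* - c) H(c, n) with instantaneous c */
        double n = y[9];
        double H = sigmoid_gate(n, parms[P_NMINUS], parms[P_EPSN]) *
                   sigmoid_gate(c, parms[P_CSTAR], parms[P_EPSC]) +
                   sigmoid_gate(parms[P_NPLUS], n, parms[P_EPSN]) *
                   sigmoid_gate(parms[P_CSTAR], c, parms[P_EPSC]);
        ydot[9] = (parms[P_CSTAR] - c) * H / parms[P_TAUSCAL];
    }
}
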