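#include <R.h>
#include <Rmath.h>

/* Generic mass-action right-hand side for deSolve's compiled-model
 * interface.  The whole network is packed into the parameter vector so a
 * single compiled routine serves any declarative network:
 *
 *   [0]                 n_species
 *   [1]                 n_reactions
 *   [2 .. 2+nr)         rate constants, one per reaction
 *   [.. nr)             number of kinetic terms per reaction
 *   [.. 2*nterms)       (species index 1-based, kinetic order) pairs,
 *                       reaction-major; covers reactants and modifiers
 *   [1]                 number of stoichiometry triplets
 *   [.. 3*nst)          (species, reaction, coefficient) triplets
 *
 * The vector is padded with zeros to MA_MAXPAR so the initializer can use
 * a fixed length.
 */

#define MA_MAXPAR 8192
#define MA_MAXRXN 512

static double ma_par[MA_MAXPAR];

void ma_init(void (*odeparms)(int *, double *))
{
    int n = MA_MAXPAR;
    odeparms(&n, ma_par);
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *p = ma_par;
    int ns = (int) p[0];
    int nr = (int) p[1];
    const double *k = p + 2;
    const double *ntermv = p + 2 + nr;
    const double *tp = ntermv + nr;
    double flux[MA_MAXRXN];
    int i, j, m;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;

    for (j = 0; j < nr; j++) {
        double f = k[j];
        int nt = (int) ntermv[j];
        for (m = 0; m < nt; m++) {
            int sp = (int) tp[0] - 1;
            int ord = (int) tp[1];
            double v = y[sp];
            if (v < 0.0) v = 0.0;  /* guard sub-tolerance excursions */
            if (ord == 1)      f *= v;
            else if (ord == 2) f *= v * v;
            else               f *= R_pow_di(v, ord);
            tp += 2;
        }
        flux[j] = f;
    }

    m = (int) tp[0];
    tp++;
    for (j = 0; j < m; j++) {
        int s = (int) tp[0] - 1;
        int r = (int) tp[1] - 1;
        ydot[s] += tp[2] * flux[r];
        tp += 3;
    }
}
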