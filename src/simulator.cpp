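// PDMP simulation core: two-state promoter switching with rates refreshed on
// a fixed grid, exact exponential waiting times within each interval, and
// closed-form integration of the linear mRNA/protein ODEs between switches.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Advance M' = s0*E - d0*M, P' = s1*M - d1*P by time t with E constant.
static inline void advance_ode(double &M, double &P, double E,
                               double s0, double d0, double s1, double d1,
                               double t) {
    const double sE = s0 * E;
    const double M0 = M, P0 = P;
    double Ms = 0.0, A = 0.0;
    if (d0 > 0.0) {
        Ms = sE / d0;
        A = M0 - Ms;
        M = Ms + A * std::exp(-d0 * t);
    } else {
        M = M0 + sE * t;
    }
    if (d1 > 0.0) {
        if (d0 > 0.0) {
            const double Ps = s1 * Ms / d1;
            if (std::fabs(d0 - d1) > 1e-9 * std::max(d0, d1)) {
                const double C = s1 * A / (d1 - d0);
                P = Ps + C * std::exp(-d0 * t) +
                    (P0 - Ps - C) * std::exp(-d1 * t);
            } else {
                // resonant case d0 == d1: secular term t * exp(-d1 t)
                P = Ps + (P0 - Ps) * std::exp(-d1 * t) +
                    s1 * A * t * std::exp(-d1 * t);
            }
        } else {
            // M grows linearly: particular solution a + b t
            const double b = s1 * sE / d1;
            const double a = (s1 * M0 - b) / d1;
            P = a + b * t + (P0 - a) * std::exp(-d1 * t);
        }
    } else {
        if (d0 > 0.0)
            P = P0 + s1 * (Ms * t + A * (1.0 - std::exp(-d0 * t)) / d0);
        else
            P = P0 + s1 * (M0 * t + 0.5 * sE * t * t);
    }
    if (M < 0.0) M = 0.0;
    if (P < 0.0) P = 0.0;
}

static inline double bounded_rate(double rmin, double rmax, double beta,
                                  double phi) {
    const double b = beta * phi;
    if (!R_finite(b)) return rmax;
    return (rmin + rmax * b) / (1.0 + b);
}

// [[Rcpp::export(name = ".simulateCells")]]
List simulateCells(NumericMatrix E0, NumericMatrix M0, NumericMatrix P0,
                   NumericMatrix thetaP, NumericMatrix thetaQ,
                   NumericVector hP, NumericVector hQ, double gamma,
                   NumericMatrix kin, LogicalVector knockedOut,
                   LogicalVector frozen, NumericVector times,
                   NumericMatrix Qmat, LogicalVector recordAfter) {
    const int n = M0.nrow();
    const int G = M0.ncol();
    const int S = thetaQ.ncol();
    const int K = times.size() - 1;  // number of intervals

    // kinetics columns: s0 d0 s1 d1 konMin konMax koffMin koffMax bKon bKoff
    std::vector<double> s0(G), d0(G), s1(G), d1(G), konMin(G), konMax(G),
        koffMin(G), koffMax(G), bKon(G), bKoff(G);
    for (int i = 0; i < G; ++i) {
        s0[i] = kin(i, 0); d0[i] = kin(i, 1);
        s1[i] = kin(i, 2); d1[i] = kin(i, 3);
        konMin[i] = kin(i, 4); konMax[i] = kin(i, 5);
        koffMin[i] = kin(i, 6); koffMax[i] = kin(i, 7);
        bKon[i] = kin(i, 8); bKoff[i] = kin(i, 9);
    }

    int nRec = 0;
    std::vector<int> recIndex(K, -1);
    for (int k = 0; k < K; ++k)
        if (recordAfter[k]) recIndex[k] = nRec++;
    List records(nRec);
    std::vector<NumericMatrix> recM;
    recM.reserve(nRec);
    for (int r = 0; r < nRec; ++r) {
        NumericMatrix m(n, G);
        recM.push_back(m);
        records[r] = m;
    }

    NumericMatrix Ef(n, G), Mf(n, G), Pf(n, G);
    std::vector<double> e(G), m(G), p(G), psnap(G), kon(G), koff(G);

    RNGScope scope;

    for (int c = 0; c < n; ++c) {
        for (int i = 0; i < G; ++i) {
            e[i] = E0(c, i); m[i] = M0(c, i); p[i] = P0(c, i);
            if (knockedOut[i]) { e[i] = 0.0; }
        }
        for (int k = 0; k < K; ++k) {
            const double dt = times[k + 1] - times[k];
            if (dt <= 0.0) continue;
            // rates frozen at interval start, from a snapshot of all proteins
            for (int i = 0; i < G; ++i) psnap[i] = p[i];
            for (int i = 0; i < G; ++i) {
                if (frozen[i] || knockedOut[i]) continue;
                double phi = 1.0;
                for (int s = 0; s < S; ++s) {
                    const double th = thetaQ(i, s);
                    if (th == 0.0) continue;
                    const double x = std::pow(Qmat(k, s) / hQ[s], gamma);
                    phi *= (1.0 + std::exp(th) * x) / (1.0 + x);
                }
                for (int j = 0; j < G; ++j) {
                    const double th = thetaP(i, j);
                    if (th == 0.0) continue;
                    const double x = std::pow(psnap[j] / hP[j], gamma);
                    phi *= (1.0 + std::exp(th) * x) / (1.0 + x);
                }
                kon[i] = bounded_rate(konMin[i], konMax[i], bKon[i], phi);
                koff[i] = bounded_rate(koffMin[i], koffMax[i], bKoff[i], phi);
            }
            for (int i = 0; i < G; ++i) {
                if (frozen[i]) continue;
                if (knockedOut[i]) {
                    // promoter forced off: pure decay
                    advance_ode(m[i], p[i], 0.0, s0[i], d0[i], s1[i], d1[i],
                                dt);
                    continue;
                }
                double tcur = 0.0;
                double Ei = e[i];
                for (;;) {
                    const double rate = (Ei > 0.5) ? koff[i] : kon[i];
                    if (rate <= 0.0) {
                        advance_ode(m[i], p[i], Ei, s0[i], d0[i], s1[i],
                                    d1[i], dt - tcur);
                        break;
                    }
                    const double w = R::exp_rand() / rate;
                    if (tcur + w >= dt) {
                        advance_ode(m[i], p[i], Ei, s0[i], d0[i], s1[i],
                                    d1[i], dt - tcur);
                        break;
                    }
                    advance_ode(m[i], p[i], Ei, s0[i], d0[i], s1[i], d1[i],
                                w);
                    Ei = 1.0 - Ei;
                    tcur += w;
                }
                e[i] = Ei;
            }
            if (recIndex[k] >= 0) {
                NumericMatrix &rec = recM[recIndex[k]];
                for (int i = 0; i < G; ++i) {
                    if (!R_finite(m[i]) || !R_finite(p[i]))
                        stop("non-finite state during simulation "
                             "(parameter blow-up?)");
                    rec(c, i) = m[i];
                }
            }
        }
        for (int i = 0; i < G; ++i) {
            Ef(c, i) = e[i]; Mf(c, i) = m[i]; Pf(c, i) = p[i];
        }
    }

    return List::create(_["records"] = records, _["E"] = Ef, _["M"] = Mf,
                        _["P"] = Pf);
}
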