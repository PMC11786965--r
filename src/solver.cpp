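// Compiled core of the Cox group-lasso path solver.
//
// The R level owns problem construction, standardization and the grid;
// this file implements the negative log partial likelihood (Breslow ties,
// normalized by n), its gradient, the group proximal operator, and a
// monotone accelerated proximal-gradient loop with backtracking, run over
// a decreasing lambda grid with warm starts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PL {
    const mat& X;        // rows sorted by decreasing follow-up time
    const ivec& status;  // aligned with X
    const uvec& tieLast; // 0-based last index of each row's tie run
    double n;
};

double pl_nll(const PL& pl, const vec& beta, vec& eta) {
    eta = pl.X * beta;
    double m = eta.max();
    vec w = exp(eta - m);
    vec cw = cumsum(w);
    double acc = 0.0;
    for (uword i = 0; i < pl.X.n_rows; ++i)
        if (pl.status[i] == 1)
            acc += eta[i] - (std::log(cw[pl.tieLast[i]]) + m);
    return -acc / pl.n;
}

vec pl_grad(const PL& pl, const vec& beta) {
    vec eta = pl.X * beta;
    double m = eta.max();
    vec w = exp(eta - m);
    vec cw = cumsum(w);
    uword nr = pl.X.n_rows;
    vec contrib(nr, fill::zeros);
    for (uword i = 0; i < nr; ++i)
        if (pl.status[i] == 1)
            contrib[pl.tieLast[i]] += 1.0 / cw[pl.tieLast[i]];
    vec r(nr);
    double acc = 0.0;
    for (uword i = nr; i-- > 0;) {
        acc += contrib[i];
        r[i] = acc;
    }
    vec a = conv_to<vec>::from(pl.status) - w % r;
    return -(pl.X.t() * a) / pl.n;
}

// group soft-threshold in place; returns beta for chaining
void group_prox(vec& v, const umat& gidx, const vec& thr) {
    for (uword b = 0; b < gidx.n_rows; ++b) {
        uword s = gidx(b, 0), e = gidx(b, 1);
        double nv = norm(v.subvec(s, e));
        if (nv <= thr[b])
            v.subvec(s, e).zeros();
        else
            v.subvec(s, e) *= (1.0 - thr[b] / nv);
    }
}

double group_pen(const vec& beta, const umat& gidx, const vec& w) {
    double p = 0.0;
    for (uword b = 0; b < gidx.n_rows; ++b)
        p += w[b] * norm(beta.subvec(gidx(b, 0), gidx(b, 1)));
    return p;
}

double kkt_resid(const PL& pl, const vec& beta, const umat& gidx,
                 const vec& w, double lambda) {
    vec g = pl_grad(pl, beta);
    double worst = 0.0;
    for (uword b = 0; b < gidx.n_rows; ++b) {
        uword s = gidx(b, 0), e = gidx(b, 1);
        double nb = norm(beta.subvec(s, e));
        double r;
        if (nb > 0)
            r = norm(g.subvec(s, e) +
                     lambda * w[b] * beta.subvec(s, e) / nb);
        else
            r = std::max(0.0, norm(g.subvec(s, e)) - lambda * w[b]);
        worst = std::max(worst, r);
    }
    return worst;
}

struct FitOne {
    vec beta;
    double objective;
    int iterations;
    bool converged;
    double L;
    double kkt;
};

FitOne solve_one(const PL& pl, const umat& gidx, const vec& w,
                 double lambda, const vec& beta0, double L0, double tol,
                 int maxIter, double kktTol) {
    vec beta = beta0, v = beta0, eta;
    double tk = 1.0, L = std::max(L0, 1e-8);
    double Q = pl_nll(pl, beta, eta) + lambda * group_pen(beta, gidx, w);
    bool converged = false;
    int it = 0;
    vec thr(w.n_elem), cand, d, g;
    while (it < maxIter) {
        ++it;
        double fv = pl_nll(pl, v, eta);
        g = pl_grad(pl, v);
        double fc;
        for (;;) { // backtracking line search
            cand = v - g / L;
            thr = lambda * w / L;
            group_prox(cand, gidx, thr);
            d = cand - v;
            fc = pl_nll(pl, cand, eta);
            if (fc <= fv + dot(g, d) + 0.5 * L * dot(d, d) + 1e-12)
                break;
            L *= 2.0;
        }
        double Qc = fc + lambda * group_pen(cand, gidx, w);
        if (Qc > Q + 1e-15) {
            // monotone fallback: plain descent step from the incumbent
            double fb = pl_nll(pl, beta, eta);
            g = pl_grad(pl, beta);
            for (;;) {
                cand = beta - g / L;
                thr = lambda * w / L;
                group_prox(cand, gidx, thr);
                d = cand - beta;
                fc = pl_nll(pl, cand, eta);
                if (fc <= fb + dot(g, d) + 0.5 * L * dot(d, d) + 1e-12)
                    break;
                L *= 2.0;
            }
            Qc = fc + lambda * group_pen(cand, gidx, w);
            v = cand;
            tk = 1.0;
        } else {
            double tk1 = (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0;
            v = cand + ((tk - 1.0) / tk1) * (cand - beta);
            tk = tk1;
        }
        double relChange = std::abs(Q - Qc) / std::max(1.0, std::abs(Q));
        beta = cand;
        Q = Qc;
        if (relChange < tol) {
            if (kkt_resid(pl, beta, gidx, w, lambda) < kktTol) {
                converged = true;
                break;
            }
            v = beta; // objective stalled before stationarity: restart
            tk = 1.0;
        }
        L = std::max(L / 1.5, 1e-8);
    }
    double kk = kkt_resid(pl, beta, gidx, w, lambda);
    return {beta, Q, it, converged || kk < kktTol, L, kk};
}

} // namespace

// [[Rcpp::export(name = ".cppFitPath")]]
Rcpp::List cppFitPath(const arma::mat& Xs, const arma::ivec& status,
                      const arma::uvec& tieLast1, const arma::umat& gidx1,
                      const arma::vec& weights, const arma::vec& lambda,
                      double tol, int maxIter, double kktTol) {
    uvec tieLast = tieLast1 - 1;  // R is 1-based
    umat gidx = gidx1 - 1;
    PL pl{Xs, status, tieLast, static_cast<double>(Xs.n_rows)};
    uword G = lambda.n_elem, p = Xs.n_cols, B = gidx.n_rows;
    mat coef(G, p, fill::zeros);
    umat active(G, B, fill::zeros);
    ivec iters(G);
    vec kkts(G), objs(G);
    Rcpp::LogicalVector conv(G);
    vec beta(p, fill::zeros);
    double L = 1.0;
    for (uword gi = 0; gi < G; ++gi) {
        FitOne fit = solve_one(pl, gidx, weights, lambda[gi], beta, L, tol,
                               maxIter, kktTol);
        beta = fit.beta;
        L = fit.L;
        coef.row(gi) = beta.t();
        for (uword b = 0; b < B; ++b)
            active(gi, b) =
                norm(beta.subvec(gidx(b, 0), gidx(b, 1))) > 0 ? 1 : 0;
        conv[gi] = fit.converged;
        iters[gi] = fit.iterations;
        kkts[gi] = fit.kkt;
        objs[gi] = fit.objective;
        if (gi % 10 == 9) Rcpp::checkUserInterrupt();
    }
    return Rcpp::List::create(
        Rcpp::Named("coef") = coef, Rcpp::Named("active") = active,
        Rcpp::Named("converged") = conv, Rcpp::Named("iterations") = iters,
        Rcpp::Named("kkt") = kkts, Rcpp::Named("objective") = objs);
}
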