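#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Markov-chain exact tests
//
// Both chains run on a latent "token" representation in which gene copies
// (or column genotypes) are distinguishable.  A uniform distribution over
// token arrangements induces exactly the conditional distribution of the
// table given its margins (random union of gametes for HWE; random
// permutation of one column for the contingency test), so a symmetric swap
// proposal is always accepted and no Metropolis ratio is needed.
// ---------------------------------------------------------------------------

static inline int cell(int a, int b, int k) {
  // lower-triangle cell index for unordered pair (a,b), 0-based alleles
  int i = a > b ? a : b, j = a > b ? b : a;
  return i * k + j;
}

// [[Rcpp::export]]
List hwe_mc_chain(IntegerMatrix genotypes, int batches, int iters, int burnin) {
  // genotypes: n x 2, allele codes 1..k, no missing rows
  int n = genotypes.nrow();
  if (n < 1) stop("no genotypes");
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (genotypes(i, 0) > k) k = genotypes(i, 0);
    if (genotypes(i, 1) > k) k = genotypes(i, 1);
  }
  std::vector<int> a1(n), a2(n);
  std::vector<double> cnt(k * k, 0.0);
  int het = 0;
  double sumLg = 0.0;
  for (int i = 0; i < n; ++i) {
    a1[i] = genotypes(i, 0) - 1;
    a2[i] = genotypes(i, 1) - 1;
    cnt[cell(a1[i], a2[i], k)] += 1.0;
    if (a1[i] != a2[i]) ++het;
  }
  for (int c = 0; c < k * k; ++c) sumLg += R::lgammafn(cnt[c] + 1.0);
  const double log2 = std::log(2.0);
  double lp_obs = het * log2 - sumLg;
  if (n == 1) return List::create(_["p"] = 1.0, _["se"] = 0.0);

  double lp_cur = lp_obs;
  NumericVector batch_p(batches);
  long total_done = 0;
  for (int b = -1; b < batches; ++b) {
    long hits = 0;
    int todo = (b < 0) ? burnin : iters;
    for (int it = 0; it < todo; ++it) {
      int u = (int)(R::unif_rand() * n);
      int v = (int)(R::unif_rand() * (n - 1));
      if (v >= u) ++v;
      int su = R::unif_rand() < 0.5 ? 0 : 1;
      int sv = R::unif_rand() < 0.5 ? 0 : 1;
      int au = su ? a2[u] : a1[u];
      int av = sv ? a2[v] : a1[v];
      if (au != av) {
        // remove old cells
        int c1 = cell(a1[u], a2[u], k), c2 = cell(a1[v], a2[v], k);
        sumLg -= R::lgammafn(cnt[c1] + 1.0); cnt[c1] -= 1.0;
        sumLg += R::lgammafn(cnt[c1] + 1.0);
        sumLg -= R::lgammafn(cnt[c2] + 1.0); cnt[c2] -= 1.0;
        sumLg += R::lgammafn(cnt[c2] + 1.0);
        het -= (a1[u] != a2[u]) + (a1[v] != a2[v]);
        // swap tokens
        if (su) a2[u] = av; else a1[u] = av;
        if (sv) a2[v] = au; else a1[v] = au;
        int n1 = cell(a1[u], a2[u], k), n2 = cell(a1[v], a2[v], k);
        sumLg -= R::lgammafn(cnt[n1] + 1.0); cnt[n1] += 1.0;
        sumLg += R::lgammafn(cnt[n1] + 1.0);
        sumLg -= R::lgammafn(cnt[n2] + 1.0); cnt[n2] += 1.0;
        sumLg += R::lgammafn(cnt[n2] + 1.0);
        het += (a1[u] != a2[u]) + (a1[v] != a2[v]);
        lp_cur = het * log2 - sumLg;
      }
      if (b >= 0 && lp_cur <= lp_obs + 1e-9) ++hits;
    }
    if (b >= 0) { batch_p[b] = (double)hits / iters; total_done += todo; }
  }
  double p = mean(batch_p);
  double se = batches > 1 ? sd(batch_p) / std::sqrt((double)batches) : NA_REAL;
  return List::create(_["p"] = p, _["se"] = se);
}

// [[Rcpp::export]]
List contingency_mc_chain(IntegerVector g1, IntegerVector g2,
                          int batches, int iters, int burnin) {
  // g1, g2: genotype class codes 1..r / 1..c per individual
  int n = g1.size();
  if (n != g2.size()) stop("length mismatch");
  int r = max(g1), c = max(g2);
  std::vector<int> x(n), y(n);
  std::vector<double> cnt(r * c, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = g1[i] - 1; y[i] = g2[i] - 1;
    cnt[x[i] * c + y[i]] += 1.0;
  }
  double sumLg = 0.0;
  for (int j = 0; j < r * c; ++j) sumLg += R::lgammafn(cnt[j] + 1.0);
  double stat_obs = -sumLg, stat_cur = stat_obs;
  if (r == 1 || c == 1) return List::create(_["p"] = 1.0, _["se"] = 0.0);

  NumericVector batch_p(batches);
  for (int b = -1; b < batches; ++b) {
    long hits = 0;
    int todo = (b < 0) ? burnin : iters;
    for (int it = 0; it < todo; ++it) {
      int u = (int)(R::unif_rand() * n);
      int v = (int)(R::unif_rand() * (n - 1));
      if (v >= u) ++v;
      if (y[u] != y[v]) {
        int c1 = x[u] * c + y[u], c2 = x[v] * c + y[v];
        int n1 = x[u] * c + y[v], n2 = x[v] * c + y[u];
        sumLg -= R::lgammafn(cnt[c1] + 1.0); cnt[c1] -= 1.0;
        sumLg += R::lgammafn(cnt[c1] + 1.0);
        sumLg -= R::lgammafn(cnt[c2] + 1.0); cnt[c2] -= 1.0;
        sumLg += R::lgammafn(cnt[c2] + 1.0);
        sumLg -= R::lgammafn(cnt[n1] + 1.0); cnt[n1] += 1.0;
        sumLg += R::lgammafn(cnt[n1] + 1.0);
        sumLg -= R::lgammafn(cnt[n2] + 1.0); cnt[n2] += 1.0;
        sumLg += R::lgammafn(cnt[n2] + 1.0);
        int tmp = y[u]; y[u] = y[v]; y[v] = tmp;
        stat_cur = -sumLg;
      }
      if (b >= 0 && stat_cur <= stat_obs + 1e-9) ++hits;
    }
    if (b >= 0) batch_p[b] = (double)hits / iters;
  }
  double p = mean(batch_p);
  double se = batches > 1 ? sd(batch_p) / std::sqrt((double)batches) : NA_REAL;
  return List::create(_["p"] = p, _["se"] = se);
}

// ---------------------------------------------------------------------------
// Coalescent microsatellite sample under IAM / SMM / TPM with a
// piecewise-constant population-size history.
//
// epoch_start: times in generations ago (ascending, first must be 0);
// epoch_N: diploid effective size in each epoch.  Mutations are placed as
// Poisson(mu * branch length) and applied root-to-tip.  Returned states are
// repeat-count offsets relative to the root (IAM mutations jump to unique
// labels >= 100000 so they never collide with stepwise states).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector coal_msat_cpp(int n, double mu, int model, double p_single,
                            double geom_p, NumericVector epoch_start,
                            NumericVector epoch_N) {
  if (n < 2) stop("need at least 2 genes");
  int nep = epoch_start.size();
  int nnode = 2 * n - 1;
  std::vector<double> tnode(nnode, 0.0);
  std::vector<int> lchild(nnode, -1), rchild(nnode, -1);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int nact = n, next_node = n, ep = 0;
  double t = 0.0;
  while (nact > 1) {
    double N = epoch_N[ep];
    double rate = nact * (nact - 1.0) / (4.0 * N);  // per generation
    double wait = R::exp_rand() / rate;
    double bound = (ep + 1 < nep) ? epoch_start[ep + 1] : R_PosInf;
    if (t + wait > bound) { t = bound; ++ep; continue; }
    t += wait;
    int i = (int)(R::unif_rand() * nact);
    int j = (int)(R::unif_rand() * (nact - 1));
    if (j >= i) ++j;
    int ni = next_node++;
    tnode[ni] = t; lchild[ni] = active[i]; rchild[ni] = active[j];
    // replace i with new node, remove j
    active[i] = ni;
    active[j] = active[nact - 1];
    --nact;
  }
  // mutate root -> tips
  std::vector<int> state(nnode, 0);
  int iam_counter = 100000;
  for (int ni = nnode - 1; ni >= n; --ni) {
    int ch[2] = { lchild[ni], rchild[ni] };
    for (int cdx = 0; cdx < 2; ++cdx) {
      int cnode = ch[cdx];
      double bl = tnode[ni] - tnode[cnode];
      int nmut = R::rpois(mu * bl);
      int s = state[ni];
      for (int m = 0; m < nmut; ++m) {
        if (model == 0) {                       // IAM
          s = ++iam_counter;
        } else if (model == 1) {                // SMM
          s += (R::unif_rand() < 0.5) ? -1 : 1;
        } else {                                // TPM
          if (R::unif_rand() < p_single) {
            s += (R::unif_rand() < 0.5) ? -1 : 1;
          } else {
            int step = 1 + (int)R::rgeom(geom_p);
            s += (R::unif_rand() < 0.5) ? -step : step;
          }
        }
      }
      state[cnode] = s;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = state[i];
  return out;
}

// Batched conditional-on-k equilibrium sampler: repeat coalescent draws,
// keep samples whose allele count equals k_target, return their unbiased
// heterozygosities.  Mirrors coal_msat_cpp with a constant size N.
// [[Rcpp::export]]
List coal_msat_hdist(int n, double mu, int model, double p_single,
                     double geom_p, double N, int k_target, int sims,
                     int max_attempts) {
  std::vector<double> hs;
  hs.reserve(sims);
  int attempts = 0;
  NumericVector es(1, 0.0), eN(1, N);
  while ((int)hs.size() < sims && attempts < max_attempts) {
    ++attempts;
    IntegerVector st = coal_msat_cpp(n, mu, model, p_single, geom_p, es, eN);
    std::map<int, int> cnt;
    for (int i = 0; i < n; ++i) ++cnt[st[i]];
    if ((int)cnt.size() != k_target) continue;
    double sump2 = 0.0;
    for (auto& kv : cnt) {
      double p = (double)kv.second / n;
      sump2 += p * p;
    }
    hs.push_back((double)n / (n - 1.0) * (1.0 - sump2));
  }
  return List::create(_["H"] = wrap(hs), _["attempts"] = attempts);
}

// ---------------------------------------------------------------------------
// Admixture-model Gibbs sampler (Pritchard-Stephens-Donnelly style).
//
// geno: N x (L * ploidy) integer matrix, columns grouped by locus
//       (locus l occupies columns l*ploidy .. l*ploidy+ploidy-1, 0-based),
//       allele codes 1..J[l], 0 = missing.
// Updates: allele frequencies P ~ Dirichlet(lambda + counts);
//          copy origins z ~ categorical(q_ik * p_klj);
//          admixture rows q_i ~ Dirichlet(alpha + m_ik);
//          alpha by a Metropolis random walk with uniform prior (0, alpha_max].
// L(K) is reported as the posterior mean of the mixture log-likelihood
// sum log(sum_k q_ik p_klj) over recorded (thinned) iterations.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector J, int ploidy,
                         int K, int burnin, int niter, double lambda,
                         double alpha0, double alpha_max, double alpha_sd,
                         int thin) {
  int N = geno.nrow(), L = J.size();
  if (geno.ncol() != L * ploidy) stop("geno/J dimension mismatch");
  if (K < 1) stop("K must be >= 1");
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + J[l];
  int Jtot = off[L];

  std::vector<int> z(N * L * ploidy, 0);
  std::vector<double> p(K * Jtot, 0.0);
  std::vector<double> q(N * K, 1.0 / K);
  std::vector<double> nP(K * Jtot, 0.0);
  std::vector<double> mQ(N * K, 0.0);
  double alpha = alpha0;

  // init z uniformly, build counts
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < ploidy; ++c) {
        int g = geno(i, l * ploidy + c);
        if (g == 0) continue;
        int zk = (int)(R::unif_rand() * K);
        z[(i * L + l) * ploidy + c] = zk;
        nP[zk * Jtot + off[l] + g - 1] += 1.0;
        mQ[i * K + zk] += 1.0;
      }

  std::vector<double> qsum(N * K, 0.0);
  std::vector<double> psum(K * Jtot, 0.0);
  std::vector<double> ll_samples;
  double alpha_sum = 0.0;
  int nrec = 0, nthin = 0;
  std::vector<double> gam(K), prob(K);

  for (int sweep = 0; sweep < burnin + niter; ++sweep) {
    // P update
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (int j = 0; j < J[l]; ++j) {
          double g = R::rgamma(lambda + nP[k * Jtot + off[l] + j], 1.0);
          p[k * Jtot + off[l] + j] = g;
          tot += g;
        }
        for (int j = 0; j < J[l]; ++j) p[k * Jtot + off[l] + j] /= tot;
      }
    // Q update
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + mQ[i * K + k], 1.0);
        gam[k] = g; tot += g;
      }
      if (tot <= 0) { for (int k = 0; k < K; ++k) gam[k] = 1.0; tot = K; }
      for (int k = 0; k < K; ++k) q[i * K + k] = gam[k] / tot;
    }
    // z update; during the first half of burn-in the conditional is
    // tempered (T > 1) so chains can cross between labelling/mode basins
    // before the landscape hardens (burn-in states are discarded, so this
    // does not bias the recorded samples)
    double invT = 1.0;
    if (sweep < burnin / 2 && burnin > 0) {
      double frac = (double)sweep / (burnin / 2.0);
      double T = 3.0 - 2.0 * frac;  // 3 -> 1 linearly
      invT = 1.0 / T;
    }
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < ploidy; ++c) {
          int g = geno(i, l * ploidy + c);
          if (g == 0) continue;
          int idx = (i * L + l) * ploidy + c;
          int zold = z[idx];
          nP[zold * Jtot + off[l] + g - 1] -= 1.0;
          mQ[i * K + zold] -= 1.0;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = q[i * K + k] * p[k * Jtot + off[l] + g - 1];
            if (invT != 1.0) prob[k] = std::pow(prob[k], invT);
            tot += prob[k];
          }
          double u = R::unif_rand() * tot, acc = 0.0;
          int znew = K - 1;
          for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { znew = k; break; } }
          z[idx] = znew;
          nP[znew * Jtot + off[l] + g - 1] += 1.0;
          mQ[i * K + znew] += 1.0;
        }
    // alpha Metropolis step (symmetric Dirichlet parameter, uniform prior).
    // alpha is held at its initial value during the first half of burn-in so
    // the admixture prior stays soft while cluster labels organise; chains
    // otherwise lock into poor modes once alpha collapses.
    if (K > 1 && sweep >= burnin / 2) {
      double aprop = alpha + R::norm_rand() * alpha_sd;
      if (aprop > 0 && aprop <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(q[i * K + k]);
        double lold = N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) + (alpha - 1.0) * slq;
        double lnew = N * (R::lgammafn(K * aprop) - K * R::lgammafn(aprop)) + (aprop - 1.0) * slq;
        if (std::log(R::unif_rand()) < lnew - lold) alpha = aprop;
      }
    }
    // record
    if (sweep >= burnin) {
      for (int i = 0; i < N * K; ++i) qsum[i] += q[i];
      alpha_sum += alpha;
      ++nrec;
      if (++nthin >= thin) {
        nthin = 0;
        double ll = 0.0;
        for (int i = 0; i < N; ++i)
          for (int l = 0; l < L; ++l)
            for (int c = 0; c < ploidy; ++c) {
              int g = geno(i, l * ploidy + c);
              if (g == 0) continue;
              double mix = 0.0;
              for (int k = 0; k < K; ++k)
                mix += q[i * K + k] * p[k * Jtot + off[l] + g - 1];
              ll += std::log(mix);
            }
        ll_samples.push_back(ll);
        for (int i = 0; i < K * Jtot; ++i) psum[i] += p[i];
      }
    }
  }
  NumericMatrix Q(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = qsum[i * K + k] / nrec;
  int nps = ll_samples.size() > 0 ? (int)ll_samples.size() : 1;
  NumericMatrix P(K, Jtot);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Jtot; ++j) P(k, j) = psum[k * Jtot + j] / nps;
  return List::create(_["Q"] = Q, _["P"] = P,
                      _["loglik"] = wrap(ll_samples),
                      _["alpha"] = alpha_sum / nrec);
}
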