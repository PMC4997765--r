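// Core numerical engines: descent partitions, single-locus pedigree likelihoods,
// the exact multi-meiosis inheritance-vector HMM, the meiosis-wise Gibbs
// ("L-") sampler, GIGI-style dense-site genotype posteriors, and the
// gene-drop coverage metric used for donor selection.
//
// Pedigree encoding (all 0-based, topologically ordered so parents precede
// offspring):
//   sire[i], dam[i]  : parent indices, -1 for founders
//   frank[i]         : founder rank (0..F-1) or -1
//   patm[i], matm[i] : meiosis indices of i's paternal/maternal gamete, -1 for
//                      founders; meiosis bit 0 = parent transmitted its own
//                      paternal slot, 1 = maternal slot
// Slot j (0 = paternal, 1 = maternal) of individual i is labels[2i + j];
// founder genes are numbered 2*frank and 2*frank + 1.
//
// Genotype observations are coded 0/1/2 alt-allele copies, -1 = missing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline void build_descent_raw(int n, const int* sire, const int* dam,
                                     const int* frank, const int* patm,
                                     const int* matm, const uint8_t* iv,
                                     int* labels) {
  for (int i = 0; i < n; ++i) {
    if (frank[i] >= 0) {
      labels[2 * i] = 2 * frank[i];
      labels[2 * i + 1] = 2 * frank[i] + 1;
    } else {
      labels[2 * i] = labels[2 * sire[i] + iv[patm[i]]];
      labels[2 * i + 1] = labels[2 * dam[i] + iv[matm[i]]];
    }
  }
}

// Union-find over founder genes with parity (XOR) constraints and forced
// alleles.  A heterozygous individual links its two slot genes with parity 1;
// a homozygote forces both its genes.  The single-locus likelihood then
// factorizes over the resulting connected components, so no enumeration over
// founder-allele assignments is needed.
struct ParityUF {
  std::vector<int> parent, rnk, forced;  // forced: -1 unset, else 0/1 at root
  std::vector<uint8_t> par;              // parity of node relative to parent
  std::vector<uint8_t> touched;
  std::vector<int> c0, c1;               // per-root parity counts (filled later)
  std::vector<int> roots;
  bool ok;

  void init(int G) {
    parent.resize(G);
    par.assign(G, 0);
    rnk.assign(G, 0);
    forced.assign(G, -1);
    touched.assign(G, 0);
    c0.assign(G, 0);
    c1.assign(G, 0);
    roots.clear();
    ok = true;
    for (int g = 0; g < G; ++g) parent[g] = g;
  }

  int find(int g, int& parity_out) {
    int root = g, p = 0;
    while (parent[root] != root) {
      p ^= par[root];
      root = parent[root];
    }
    int cur = g, cum = p;
    while (parent[cur] != root) {
      int nxt = parent[cur];
      int nxtpar = par[cur];
      parent[cur] = root;
      par[cur] = (uint8_t)cum;
      cum ^= nxtpar;
      cur = nxt;
    }
    parity_out = p;
    return root;
  }

  void force(int g, int v) {
    int q;
    int r = find(g, q);
    int rv = v ^ q;
    if (forced[r] == -1)
      forced[r] = rv;
    else if (forced[r] != rv)
      ok = false;
  }

  void unite(int g1, int g2, int rel) {  // allele(g1) XOR allele(g2) == rel
    int q1, q2;
    int r1 = find(g1, q1), r2 = find(g2, q2);
    if (r1 == r2) {
      if ((q1 ^ q2) != rel) ok = false;
      return;
    }
    int x = q1 ^ q2 ^ rel;  // allele(r2) = allele(r1) XOR x (symmetric)
    if (rnk[r1] < rnk[r2]) std::swap(r1, r2);
    parent[r2] = r1;
    par[r2] = (uint8_t)x;
    if (rnk[r1] == rnk[r2]) rnk[r1]++;
    if (forced[r2] != -1) {
      int rv = forced[r2] ^ x;
      if (forced[r1] == -1)
        forced[r1] = rv;
      else if (forced[r1] != rv)
        ok = false;
      forced[r2] = -1;
    }
  }

  // Apply all constraints from observed genotypes; false on contradiction.
  bool constrain(int n, const int* labels, const int* obs) {
    for (int i = 0; i < n; ++i) {
      int o = obs[i];
      if (o < 0) continue;
      int g1 = labels[2 * i], g2 = labels[2 * i + 1];
      touched[g1] = 1;
      touched[g2] = 1;
      if (o == 0) {
        force(g1, 0);
        force(g2, 0);
      } else if (o == 2) {
        force(g1, 1);
        force(g2, 1);
      } else {
        if (g1 == g2) return false;
        unite(g1, g2, 1);
      }
      if (!ok) return false;
    }
    return true;
  }

  // Tabulate per-root parity counts over touched genes.
  void tabulate(int G) {
    for (int g = 0; g < G; ++g) {
      if (!touched[g]) continue;
      int q;
      int r = find(g, q);
      if (c0[r] + c1[r] == 0) roots.push_back(r);
      if (q == 0)
        c0[r]++;
      else
        c1[r]++;
    }
  }
};

// Likelihood of the observed genotypes at one marker given a descent
// partition: sum over founder-allele assignments of prod freq * consistency.
static double locus_lik(int n, const int* labels, const int* obs, double p,
                        int G, ParityUF& uf) {
  uf.init(G);
  if (!uf.constrain(n, labels, obs)) return 0.0;
  uf.tabulate(G);
  double lik = 1.0;
  for (size_t k = 0; k < uf.roots.size(); ++k) {
    int r = uf.roots[k];
    int n0 = uf.c0[r], n1 = uf.c1[r];
    if (uf.forced[r] != -1) {
      int a = (uf.forced[r] == 1) ? n0 : n1;  // genes carrying the alt allele
      int b = n0 + n1 - a;
      lik *= std::pow(p, a) * std::pow(1.0 - p, b);
    } else {
      double w0 = std::pow(p, n1) * std::pow(1.0 - p, n0);  // root = ref
      double w1 = std::pow(p, n0) * std::pow(1.0 - p, n1);  // root = alt
      lik *= w0 + w1;
    }
  }
  return lik;
}

// [[Rcpp::export]]
IntegerVector cpp_build_descent(IntegerVector sire, IntegerVector dam,
                                IntegerVector frank, IntegerVector patm,
                                IntegerVector matm, IntegerVector iv) {
  int n = sire.size();
  std::vector<uint8_t> bits(iv.size());
  for (int j = 0; j < iv.size(); ++j) bits[j] = (uint8_t)iv[j];
  IntegerVector labels(2 * n);
  std::vector<int> lab(2 * n);
  build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                    bits.data(), lab.data());
  for (int k = 0; k < 2 * n; ++k) labels[k] = lab[k];
  return labels;
}

// [[Rcpp::export]]
double cpp_locus_likelihood(IntegerVector labels, IntegerVector obs, double p,
                            int n_genes) {
  int n = obs.size();
  ParityUF uf;
  std::vector<int> lab(labels.begin(), labels.end());
  std::vector<int> ob(obs.begin(), obs.end());
  return locus_lik(n, lab.data(), ob.data(), p, n_genes, uf);
}

// ---------------------------------------------------------------------------
// Exact forward-backward over the 2^m inheritance-vector state space.
// Transitions factorize per meiosis, so one HMM step is m in-place
// butterfly passes instead of a dense 2^m x 2^m product.
// ---------------------------------------------------------------------------

static void mix_bits(std::vector<double>& f, int m, double theta) {
  int S = 1 << m;
  for (int b = 0; b < m; ++b) {
    int mask = 1 << b;
    for (int s = 0; s < S; ++s) {
      if (s & mask) continue;
      double f0 = f[s], f1 = f[s | mask];
      f[s] = (1.0 - theta) * f0 + theta * f1;
      f[s | mask] = theta * f0 + (1.0 - theta) * f1;
    }
  }
}

// [[Rcpp::export]]
List cpp_exact_fb(IntegerVector sire, IntegerVector dam, IntegerVector frank,
                  IntegerVector patm, IntegerVector matm, IntegerMatrix obs,
                  NumericVector theta, NumericVector p, int m, int n_samples,
                  bool want_marginals) {
  int n = sire.size();
  int T = obs.ncol();
  int S = 1 << m;
  int G = 2 * n;
  ParityUF uf;
  std::vector<int> lab(2 * n);
  std::vector<uint8_t> bits(m);
  std::vector<int> ob(n);

  // emissions
  std::vector<std::vector<double> > E((size_t)T, std::vector<double>(S));
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) ob[i] = obs(i, t);
    for (int s = 0; s < S; ++s) {
      for (int j = 0; j < m; ++j) bits[j] = (s >> j) & 1;
      build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                        bits.data(), lab.data());
      E[t][s] = locus_lik(n, lab.data(), ob.data(), p[t], G, uf);
    }
  }

  // scaled forward
  std::vector<std::vector<double> > alpha((size_t)T, std::vector<double>(S));
  std::vector<double> f(S, 1.0 / S);
  for (int t = 0; t < T; ++t) {
    if (t > 0) mix_bits(f, m, theta[t - 1]);
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      f[s] *= E[t][s];
      tot += f[s];
    }
    if (tot <= 0.0)
      stop("zero likelihood at marker %d: genotypes are Mendelian-impossible",
           t + 1);
    for (int s = 0; s < S; ++s) f[s] /= tot;
    alpha[t] = f;
  }

  NumericMatrix marg;
  if (want_marginals) {
    marg = NumericMatrix(T, S);
    std::vector<double> b(S, 1.0);
    for (int t = T - 1; t >= 0; --t) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) tot += alpha[t][s] * b[s];
      for (int s = 0; s < S; ++s) marg(t, s) = alpha[t][s] * b[s] / tot;
      if (t > 0) {
        for (int s = 0; s < S; ++s) b[s] *= E[t][s];
        mix_bits(b, m, theta[t - 1]);
        double mx = 0.0;
        for (int s = 0; s < S; ++s)
          if (b[s] > mx) mx = b[s];
        for (int s = 0; s < S; ++s) b[s] /= mx;
      }
    }
  }

  IntegerMatrix samples(n_samples, T);
  if (n_samples > 0) {
    // transition weight lookup per Hamming distance, per interval
    std::vector<std::vector<double> > powk((size_t)(T > 1 ? T - 1 : 0),
                                           std::vector<double>(m + 1));
    for (int t = 0; t + 1 < T; ++t)
      for (int k = 0; k <= m; ++k)
        powk[t][k] = std::pow(theta[t], k) * std::pow(1.0 - theta[t], m - k);
    std::vector<double> w(S);
    for (int r = 0; r < n_samples; ++r) {
      // draw final state from alpha_T
      double u = unif_rand();
      int s_next = S - 1;
      double acc = 0.0;
      for (int s = 0; s < S; ++s) {
        acc += alpha[T - 1][s];
        if (u <= acc) {
          s_next = s;
          break;
        }
      }
      samples(r, T - 1) = s_next;
      for (int t = T - 2; t >= 0; --t) {
        double tot = 0.0;
        for (int s = 0; s < S; ++s) {
          int k = __builtin_popcount((unsigned)(s ^ s_next));
          w[s] = alpha[t][s] * powk[t][k];
          tot += w[s];
        }
        u = unif_rand() * tot;
        acc = 0.0;
        int pick = S - 1;
        for (int s = 0; s < S; ++s) {
          acc += w[s];
          if (u <= acc) {
            pick = s;
            break;
          }
        }
        samples(r, t) = pick;
        s_next = pick;
      }
    }
  }

  return List::create(_["samples"] = samples, _["marginals"] = marg);
}

// ---------------------------------------------------------------------------
// Blocked Gibbs sampler over inheritance vectors: each update resamples, for
// one parent, the entire bit paths of all meioses involving that parent's
// children (both meioses of each child) jointly from their conditional
// 2^q-state HMM along the chromosome, holding all other meioses fixed.
// Sibship-blocked updates (rather than one meiosis or one individual at a
// time) are needed for mixing: with fully observed genotypes, consistent
// inheritance vectors at a marker differ by several bits (parental-phase
// coupling across siblings), so smaller moves are blocked or metastable.
// Founder-phase flip moves (swapping a founder's two gene labels, i.e.
// flipping the corresponding meiosis bit of each of its children at every
// marker) are an exact symmetry of the likelihood and mix the chain across
// the global phase modes that Gibbs updates reach only geometrically slowly.
// Large sibships are chunked so a block never exceeds 2^8 states.
// ---------------------------------------------------------------------------

// Find a per-marker Mendelian-consistent inheritance vector by conditional
// gene dropping: founder slot alleles are drawn consistent with the founder's
// observed genotype, and each non-founder's two meiosis bits are drawn
// uniformly from the combinations consistent with its own genotype.
static bool consistent_column(int n, const int* sire, const int* dam,
                              const int* frank, const int* patm,
                              const int* matm, const int* obs, double p,
                              int max_restarts, uint8_t* col,
                              long* attempts_used) {
  std::vector<uint8_t> allele(2 * n);
  for (int att = 0; att < max_restarts; ++att) {
    (*attempts_used)++;
    bool fail = false;
    for (int i = 0; i < n && !fail; ++i) {
      int o = obs[i];
      if (frank[i] >= 0) {
        if (o == 0) {
          allele[2 * i] = 0;
          allele[2 * i + 1] = 0;
        } else if (o == 2) {
          allele[2 * i] = 1;
          allele[2 * i + 1] = 1;
        } else if (o == 1) {
          int first = (unif_rand() < 0.5) ? 1 : 0;
          allele[2 * i] = (uint8_t)first;
          allele[2 * i + 1] = (uint8_t)(1 - first);
        } else {
          allele[2 * i] = (uint8_t)(unif_rand() < p);
          allele[2 * i + 1] = (uint8_t)(unif_rand() < p);
        }
      } else {
        int ok_b1[4], ok_b2[4], n_ok = 0;
        for (int b1 = 0; b1 < 2; ++b1) {
          for (int b2 = 0; b2 < 2; ++b2) {
            int a1 = allele[2 * sire[i] + b1];
            int a2 = allele[2 * dam[i] + b2];
            if (o < 0 || a1 + a2 == o) {
              ok_b1[n_ok] = b1;
              ok_b2[n_ok] = b2;
              n_ok++;
            }
          }
        }
        if (n_ok == 0) {
          fail = true;
          break;
        }
        int pick = (int)(unif_rand() * n_ok);
        if (pick >= n_ok) pick = n_ok - 1;
        col[patm[i]] = (uint8_t)ok_b1[pick];
        col[matm[i]] = (uint8_t)ok_b2[pick];
        allele[2 * i] = allele[2 * sire[i] + ok_b1[pick]];
        allele[2 * i + 1] = allele[2 * dam[i] + ok_b2[pick]];
      }
    }
    if (!fail) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_mcmc(IntegerVector sire, IntegerVector dam, IntegerVector frank,
              IntegerVector patm, IntegerVector matm, IntegerMatrix obs,
              NumericVector theta, NumericVector p, int m, int n_samples,
              int burn_in, int thin, int max_restarts) {
  int n = sire.size();
  int T = obs.ncol();
  int G = 2 * n;
  std::vector<uint8_t> B((size_t)m * T);  // column-major: B[t*m + j]
  std::vector<int> ob(n);
  long attempts = 0;

  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) ob[i] = obs(i, t);
    if (!consistent_column(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                           ob.data(), p[t], max_restarts, &B[(size_t)t * m],
                           &attempts))
      stop("no Mendelian-consistent inheritance vector found at marker %d "
           "within %d attempts",
           t + 1, max_restarts);
  }

  ParityUF uf;
  std::vector<int> lab(2 * n);
  // update blocks: for each parent, both meioses of each of its children,
  // chunked so one block holds at most 4 children (2^8 states)
  std::vector<std::vector<int> > blocks;
  for (int i = 0; i < n; ++i) {
    std::vector<int> kids;
    for (int c = 0; c < n; ++c)
      if (sire[c] == i || dam[c] == i) kids.push_back(c);
    for (size_t k0 = 0; k0 < kids.size(); k0 += 4) {
      std::vector<int> ms;
      for (size_t k = k0; k < kids.size() && k < k0 + 4; ++k) {
        ms.push_back(patm[kids[k]]);
        ms.push_back(matm[kids[k]]);
      }
      if (!ms.empty()) blocks.push_back(ms);
    }
  }
  int nb = (int)blocks.size();
  int qmax = 0;
  for (int b = 0; b < nb; ++b)
    qmax = std::max(qmax, (int)blocks[b].size());
  int Smax = 1 << qmax;
  std::vector<double> E((size_t)T * Smax), F((size_t)T * Smax);
  std::vector<double> powk((size_t)qmax + 1), w(Smax);
  std::vector<int> obs_all(obs.begin(), obs.end());  // column-major n x T
  // meioses descending from each founder (one per child), for phase flips
  std::vector<std::vector<int> > fmeio;
  for (int i = 0; i < n; ++i) {
    if (frank[i] < 0) continue;
    std::vector<int> ms;
    for (int c = 0; c < n; ++c) {
      if (sire[c] == i) ms.push_back(patm[c]);
      if (dam[c] == i) ms.push_back(matm[c]);
    }
    fmeio.push_back(ms);
  }
  std::vector<int> order(nb);
  IntegerMatrix samples(n_samples, T);
  int kept = 0;
  int total_sweeps = burn_in + n_samples * thin;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int b = 0; b < nb; ++b) order[b] = b;
    for (int b = nb - 1; b > 0; --b) {  // Fisher-Yates
      int k = (int)(unif_rand() * (b + 1));
      if (k > b) k = b;
      std::swap(order[b], order[k]);
    }
    for (int bb = 0; bb < nb; ++bb) {
      const std::vector<int>& ms = blocks[order[bb]];
      int q = (int)ms.size();
      int S = 1 << q;
      // emissions for all 2^q bit combinations per marker
      for (int t = 0; t < T; ++t) {
        uint8_t* col = &B[(size_t)t * m];
        uint8_t saved[8];
        for (int j = 0; j < q; ++j) saved[j] = col[ms[j]];
        const int* obt = &obs_all[(size_t)t * n];
        for (int c = 0; c < S; ++c) {
          for (int j = 0; j < q; ++j)
            col[ms[j]] = (uint8_t)((c >> j) & 1);
          build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0],
                            &matm[0], col, lab.data());
          E[(size_t)t * Smax + c] =
              locus_lik(n, lab.data(), obt, p[t], G, uf);
        }
        for (int j = 0; j < q; ++j) col[ms[j]] = saved[j];
      }
      // 2^q-state forward with scaling; transitions factorize per meiosis
      for (int t = 0; t < T; ++t) {
        double* f = &F[(size_t)t * Smax];
        const double* e = &E[(size_t)t * Smax];
        if (t == 0) {
          for (int c = 0; c < S; ++c) f[c] = e[c];
        } else {
          double th = theta[t - 1];
          for (int k = 0; k <= q; ++k)
            powk[k] = std::pow(th, k) * std::pow(1.0 - th, q - k);
          const double* fp = &F[(size_t)(t - 1) * Smax];
          for (int c = 0; c < S; ++c) {
            double acc = 0.0;
            for (int cp = 0; cp < S; ++cp)
              acc += fp[cp] * powk[__builtin_popcount((unsigned)(c ^ cp))];
            f[c] = acc * e[c];
          }
        }
        double tot = 0.0;
        for (int c = 0; c < S; ++c) tot += f[c];
        if (tot <= 0.0)
          stop("likelihood collapsed during sampling at marker %d", t + 1);
        for (int c = 0; c < S; ++c) f[c] /= tot;
      }
      // backward sampling of the joint block path
      double u = unif_rand();
      int cprev = S - 1;
      {
        const double* f = &F[(size_t)(T - 1) * Smax];
        double acc = 0.0;
        for (int c = 0; c < S; ++c) {
          acc += f[c];
          if (u <= acc) {
            cprev = c;
            break;
          }
        }
      }
      for (int j = 0; j < q; ++j)
        B[(size_t)(T - 1) * m + ms[j]] = (uint8_t)((cprev >> j) & 1);
      for (int t = T - 2; t >= 0; --t) {
        double th = theta[t];
        for (int k = 0; k <= q; ++k)
          powk[k] = std::pow(th, k) * std::pow(1.0 - th, q - k);
        const double* f = &F[(size_t)t * Smax];
        double tot = 0.0;
        for (int c = 0; c < S; ++c) {
          w[c] = f[c] * powk[__builtin_popcount((unsigned)(c ^ cprev))];
          tot += w[c];
        }
        u = unif_rand() * tot;
        double acc = 0.0;
        int pick = S - 1;
        for (int c = 0; c < S; ++c) {
          acc += w[c];
          if (u <= acc) {
            pick = c;
            break;
          }
        }
        for (int j = 0; j < q; ++j)
          B[(size_t)t * m + ms[j]] = (uint8_t)((pick >> j) & 1);
        cprev = pick;
      }
    }
    // founder-phase flips: exact symmetry moves, accepted with prob 1/2
    for (size_t fi = 0; fi < fmeio.size(); ++fi) {
      if (unif_rand() < 0.5) continue;
      const std::vector<int>& ms = fmeio[fi];
      for (size_t k = 0; k < ms.size(); ++k) {
        int j = ms[k];
        for (int t = 0; t < T; ++t) B[(size_t)t * m + j] ^= 1;
      }
    }
    if (sweep >= burn_in && (sweep - burn_in) % thin == thin - 1) {
      for (int t = 0; t < T; ++t) {
        int v = 0;
        for (int j = 0; j < m; ++j)
          if (B[(size_t)t * m + j]) v |= (1 << j);
        samples(kept, t) = v;
      }
      kept++;
      if (kept >= n_samples) break;
    }
  }
  return List::create(_["samples"] = samples, _["init_attempts"] = attempts);
}

// ---------------------------------------------------------------------------
// GIGI-style dense-site posteriors: for each retained framework IV sample,
// draw dense-position bits per meiosis from the flanking-interval
// interpolation, build the descent partition, condition founder-gene alleles
// on the observed dense genotypes, and average the per-individual genotype
// and per-slot allele posteriors.
// ---------------------------------------------------------------------------

struct GeneDist {
  int type;      // 0 free, 1 fixed, 2 component
  double palt;   // P(alt) for free/fixed
  int root;
  int parity;
};

// [[Rcpp::export]]
List cpp_dense_posterior(IntegerVector sire, IntegerVector dam,
                         IntegerVector frank, IntegerVector patm,
                         IntegerVector matm, IntegerMatrix iv_samples,
                         NumericVector fw_cm, NumericVector dense_cm,
                         IntegerMatrix dense_obs, NumericVector p_dense, int m,
                         int k_dense) {
  int n = sire.size();
  int S = iv_samples.nrow();
  int T = fw_cm.size();
  int D = dense_cm.size();
  int G = 2 * n;

  NumericMatrix P_RR(n, D), P_RA(n, D), P_AA(n, D), A1(n, D), A2(n, D);
  IntegerVector n_bad(D), n_reals(D);

  ParityUF uf;
  std::vector<int> lab(2 * n);
  std::vector<uint8_t> bits(m);
  std::vector<int> ob(n);
  std::vector<double> wroot0(G), wroot1(G);
  std::vector<GeneDist> gd(G);

  for (int d = 0; d < D; ++d) {
    double pos = dense_cm[d];
    double p = p_dense[d];
    // flanking framework markers
    int tl = -1, tr = T;
    {
      int lo = 0, hi = T;  // first index with fw_cm > pos
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (fw_cm[mid] > pos)
          hi = mid;
        else
          lo = mid + 1;
      }
      tr = lo;
      tl = lo - 1;
    }
    double thl = 0.0, thr = 0.0;
    bool has_l = tl >= 0, has_r = tr < T;
    if (has_l) thl = 0.5 * (1.0 - std::exp(-2.0 * (pos - fw_cm[tl]) / 100.0));
    if (has_r) thr = 0.5 * (1.0 - std::exp(-2.0 * (fw_cm[tr] - pos) / 100.0));

    for (int i = 0; i < n; ++i) ob[i] = dense_obs(i, d);

    int good = 0, bad = 0;
    for (int s = 0; s < S; ++s) {
      int ivl = has_l ? iv_samples(s, tl) : 0;
      int ivr = has_r ? iv_samples(s, tr) : 0;
      for (int k = 0; k < k_dense; ++k) {
        for (int j = 0; j < m; ++j) {
          double pr0;
          if (has_l && has_r) {
            int bl = (ivl >> j) & 1, br = (ivr >> j) & 1;
            double n0 = (bl == 0 ? 1.0 - thl : thl) *
                        (br == 0 ? 1.0 - thr : thr);
            double n1 = (bl == 1 ? 1.0 - thl : thl) *
                        (br == 1 ? 1.0 - thr : thr);
            pr0 = (n0 + n1 > 0.0) ? n0 / (n0 + n1) : 0.5;
          } else if (has_l) {
            int bl = (ivl >> j) & 1;
            pr0 = (bl == 0) ? 1.0 - thl : thl;
          } else {
            int br = (ivr >> j) & 1;
            pr0 = (br == 0) ? 1.0 - thr : thr;
          }
          bits[j] = (unif_rand() < pr0) ? 0 : 1;
        }
        build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                          bits.data(), lab.data());
        uf.init(G);
        if (!uf.constrain(n, lab.data(), ob.data())) {
          bad++;
          continue;
        }
        uf.tabulate(G);
        for (size_t rr = 0; rr < uf.roots.size(); ++rr) {
          int r = uf.roots[rr];
          wroot0[r] = std::pow(p, uf.c1[r]) * std::pow(1.0 - p, uf.c0[r]);
          wroot1[r] = std::pow(p, uf.c0[r]) * std::pow(1.0 - p, uf.c1[r]);
        }
        for (int g = 0; g < G; ++g) {
          if (!uf.touched[g]) {
            gd[g].type = 0;
            gd[g].palt = p;
          } else {
            int q;
            int r = uf.find(g, q);
            if (uf.forced[r] != -1) {
              gd[g].type = 1;
              gd[g].palt = (double)(uf.forced[r] ^ q);
            } else {
              gd[g].type = 2;
              gd[g].root = r;
              gd[g].parity = q;
              gd[g].palt = 0.0;  // filled per use
            }
          }
        }
        good++;
        for (int i = 0; i < n; ++i) {
          int g1 = lab[2 * i], g2 = lab[2 * i + 1];
          double prr, pra, paa, a1, a2;
          if (g1 == g2) {
            double px;
            if (gd[g1].type == 2) {
              int r = gd[g1].root;
              double pr1 = wroot1[r] / (wroot0[r] + wroot1[r]);
              px = gd[g1].parity ? 1.0 - pr1 : pr1;
            } else {
              px = gd[g1].palt;
            }
            paa = px;
            prr = 1.0 - px;
            pra = 0.0;
            a1 = a2 = px;
          } else if (gd[g1].type == 2 && gd[g2].type == 2 &&
                     gd[g1].root == gd[g2].root) {
            int r = gd[g1].root;
            double pr1 = wroot1[r] / (wroot0[r] + wroot1[r]);
            // root = ref: alleles (parity1, parity2); root = alt: flipped
            int x1 = gd[g1].parity, x2 = gd[g2].parity;
            double w_ref = 1.0 - pr1;
            prr = pra = paa = 0.0;
            int s_ref = x1 + x2, s_alt = (1 - x1) + (1 - x2);
            if (s_ref == 0) prr += w_ref;
            else if (s_ref == 1) pra += w_ref;
            else paa += w_ref;
            if (s_alt == 0) prr += pr1;
            else if (s_alt == 1) pra += pr1;
            else paa += pr1;
            a1 = x1 * w_ref + (1 - x1) * pr1;
            a2 = x2 * w_ref + (1 - x2) * pr1;
          } else {
            double pa, pb;
            if (gd[g1].type == 2) {
              int r = gd[g1].root;
              double pr1 = wroot1[r] / (wroot0[r] + wroot1[r]);
              pa = gd[g1].parity ? 1.0 - pr1 : pr1;
            } else
              pa = gd[g1].palt;
            if (gd[g2].type == 2) {
              int r = gd[g2].root;
              double pr1 = wroot1[r] / (wroot0[r] + wroot1[r]);
              pb = gd[g2].parity ? 1.0 - pr1 : pr1;
            } else
              pb = gd[g2].palt;
            prr = (1.0 - pa) * (1.0 - pb);
            paa = pa * pb;
            pra = pa * (1.0 - pb) + (1.0 - pa) * pb;
            a1 = pa;
            a2 = pb;
          }
          P_RR(i, d) += prr;
          P_RA(i, d) += pra;
          P_AA(i, d) += paa;
          A1(i, d) += a1;
          A2(i, d) += a2;
        }
      }
    }
    n_bad[d] = bad;
    n_reals[d] = good;
    if (good > 0) {
      for (int i = 0; i < n; ++i) {
        P_RR(i, d) /= good;
        P_RA(i, d) /= good;
        P_AA(i, d) /= good;
        A1(i, d) /= good;
        A2(i, d) /= good;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        P_RR(i, d) = NA_REAL;
        P_RA(i, d) = NA_REAL;
        P_AA(i, d) = NA_REAL;
        A1(i, d) = NA_REAL;
        A2(i, d) = NA_REAL;
      }
    }
  }
  return List::create(_["p_rr"] = P_RR, _["p_ra"] = P_RA, _["p_aa"] = P_AA,
                      _["slot1_alt"] = A1, _["slot2_alt"] = A2,
                      _["n_inconsistent"] = n_bad,
                      _["n_realizations"] = n_reals);
}

// ---------------------------------------------------------------------------
// Gene-drop coverage metric: expected fraction of allele slots whose founder
// gene is carried by a selected individual, at a single unlinked locus.
// ---------------------------------------------------------------------------

// Genotype-integrated coverage: Monte-Carlo over gene drops AND founder
// alleles; a slot counts as called when the donors' genotypes actually
// determine its founder gene's allele (forced directly by a homozygous
// carrier or through the parity constraint graph).
// [[Rcpp::export]]
List cpp_coverage_geno(IntegerVector sire, IntegerVector dam,
                       IntegerVector frank, IntegerVector patm,
                       IntegerVector matm, LogicalVector selected, int m,
                       int n_draws, double p, bool include_selected) {
  int n = sire.size();
  int G = 2 * n;
  std::vector<int> lab(2 * n);
  std::vector<uint8_t> bits(m > 0 ? m : 1);
  std::vector<uint8_t> allele(G);
  std::vector<int> obs(n);
  ParityUF uf;

  int denom = 0;
  for (int i = 0; i < n; ++i)
    if (include_selected || !selected[i]) denom += 2;
  if (denom == 0) stop("no individuals to evaluate coverage over");

  double sum = 0.0, sumsq = 0.0;
  for (int rep = 0; rep < n_draws; ++rep) {
    for (int j = 0; j < m; ++j) bits[j] = (unif_rand() < 0.5) ? 0 : 1;
    build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                      bits.data(), lab.data());
    for (int g = 0; g < G; ++g) allele[g] = (unif_rand() < p) ? 1 : 0;
    for (int i = 0; i < n; ++i)
      obs[i] = selected[i] ? allele[lab[2 * i]] + allele[lab[2 * i + 1]]
                           : -1;
    uf.init(G);
    uf.constrain(n, lab.data(), obs.data());  // consistent by construction
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (selected[i]) {
        // a sequenced individual's own allele copies are directly observed
        if (include_selected) cnt += 2;
        continue;
      }
      for (int s = 0; s < 2; ++s) {
        int g = lab[2 * i + s];
        if (!uf.touched[g]) continue;
        int q;
        int r = uf.find(g, q);
        if (uf.forced[r] != -1) cnt++;
      }
    }
    double v = (double)cnt / denom;
    sum += v;
    sumsq += v * v;
  }
  double mean = sum / n_draws;
  double se = 0.0;
  if (n_draws > 1) {
    double var = (sumsq - sum * sum / n_draws) / (n_draws - 1);
    if (var < 0) var = 0;
    se = std::sqrt(var / n_draws);
  }
  return List::create(_["coverage"] = mean, _["se"] = se,
                      _["n_draws"] = (double)n_draws);
}

// [[Rcpp::export]]
List cpp_coverage(IntegerVector sire, IntegerVector dam, IntegerVector frank,
                  IntegerVector patm, IntegerVector matm,
                  LogicalVector selected, int m, bool exact, int n_draws,
                  bool include_selected) {
  int n = sire.size();
  int G = 2 * n;
  std::vector<int> lab(2 * n);
  std::vector<uint8_t> bits(m > 0 ? m : 1);
  std::vector<uint8_t> covered(G);

  int denom = 0;
  for (int i = 0; i < n; ++i)
    if (include_selected || !selected[i]) denom += 2;
  if (denom == 0) stop("no individuals to evaluate coverage over");

  double sum = 0.0, sumsq = 0.0;
  long reps = exact ? (1L << m) : n_draws;
  for (long rep = 0; rep < reps; ++rep) {
    if (exact) {
      for (int j = 0; j < m; ++j) bits[j] = (rep >> j) & 1;
    } else {
      for (int j = 0; j < m; ++j) bits[j] = (unif_rand() < 0.5) ? 0 : 1;
    }
    build_descent_raw(n, &sire[0], &dam[0], &frank[0], &patm[0], &matm[0],
                      bits.data(), lab.data());
    std::fill(covered.begin(), covered.end(), 0);
    for (int i = 0; i < n; ++i) {
      if (!selected[i]) continue;
      covered[lab[2 * i]] = 1;
      covered[lab[2 * i + 1]] = 1;
    }
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (!include_selected && selected[i]) continue;
      cnt += covered[lab[2 * i]] + covered[lab[2 * i + 1]];
    }
    double v = (double)cnt / denom;
    sum += v;
    sumsq += v * v;
  }
  double mean = sum / reps;
  double se = 0.0;
  if (!exact && reps > 1) {
    double var = (sumsq - sum * sum / reps) / (reps - 1);
    if (var < 0) var = 0;
    se = std::sqrt(var / reps);
  }
  return List::create(_["coverage"] = mean, _["se"] = se,
                      _["n_draws"] = (double)reps);
}
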