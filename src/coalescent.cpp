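// Structured-coalescent simulation for a two-deme isolation-migration model
// with piecewise-constant diploid deme sizes and backward per-lineage
// migration rates.  Time is measured in generations before present.
//
// The model is passed as parallel epoch arrays (start, N_west, N_east,
// m_west, m_east) plus the index of the epoch at whose start all lineages
// are merged into deme 0 (the ancestral deme, whose size is that epoch's
// N_west).  m_west is the backward rate at which a lineage currently in the
// western deme jumps to the eastern deme, and vice versa.
//
// Expected joint-SFS cell masses are obtained by accumulating branch length
// per (i, j) descendant-count class (Rao-Blackwellized: no mutations are
// dropped), so the relative class masses converge with O(1/sqrt(n_sims))
// error and no Poisson mutation noise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double COLLAPSE_RATIO = 200.0;  // migration events per pair-coalescence
static const double COLLAPSE_EQUIL = 20.0;   // migration events per lineage per epoch

struct Epoch {
  double start;
  double Nw, Ne;
  double mw, me;      // backward rates: west->east, east->west
  bool collapsed;     // strong-migration panmictic approximation
  double pi_w;        // stationary P(lineage in west) when collapsed
  double lam_pair;    // per-pair coalescence rate when collapsed
};

struct Lineage {
  int deme;           // 0 = west, 1 = east
  int ci, cj;         // descendant sample counts (west, east)
  double birth;       // time the lineage came into existence
  int node;           // node id (genealogy mode), -1 otherwise
  int desc;           // index into descendant-set store (locus mode), -1 otherwise
};

// Precompute epochs, flagging those where migration is so much faster than
// coalescence that lineage locations equilibrate essentially instantly
// (strong-migration limit: pair coalescence at pi_w^2/(2Nw) + pi_e^2/(2Ne)).
static std::vector<Epoch> prepare_epochs(const NumericVector& starts,
                                         const NumericVector& Nw,
                                         const NumericVector& Ne,
                                         const NumericVector& mw,
                                         const NumericVector& me,
                                         int merge_epoch) {
  int nE = starts.size();
  std::vector<Epoch> ep(nE);
  for (int e = 0; e < nE; ++e) {
    ep[e].start = starts[e];
    ep[e].Nw = Nw[e];
    ep[e].Ne = Ne[e];
    ep[e].mw = (e >= merge_epoch) ? 0.0 : mw[e];
    ep[e].me = (e >= merge_epoch) ? 0.0 : me[e];
    ep[e].collapsed = false;
    ep[e].pi_w = 1.0;
    ep[e].lam_pair = 0.0;
    double mtot = ep[e].mw + ep[e].me;
    if (mtot > 0.0) {
      double pw = ep[e].me / mtot;           // stationary fraction in west
      double lp = pw * pw / (2.0 * ep[e].Nw) +
                  (1.0 - pw) * (1.0 - pw) / (2.0 * ep[e].Ne);
      double len = (e + 1 < nE) ? (starts[e + 1] - starts[e]) : R_PosInf;
      bool equil = !R_finite(len) || mtot * len > COLLAPSE_EQUIL;
      if (lp > 0 && mtot > COLLAPSE_RATIO * lp && equil) {
        ep[e].collapsed = true;
        ep[e].pi_w = pw;
        ep[e].lam_pair = lp;
      }
    }
  }
  return ep;
}

struct SimRecorders {
  // class totals (always)
  std::vector<double>* totals;   // (nw+1) x (ne+1), column-major [ci + cj*(nw+1)]
  double* sum_len;
  int nw1;
  // genealogy mode
  bool record_tree;
  std::vector<double>* node_time;     // per internal node
  std::vector<int>* edge_child;       // child node of each closed branch
  std::vector<int>* edge_parent;
  std::vector<double>* edge_len;
  std::vector<int>* edge_ci;
  std::vector<int>* edge_cj;
  // locus mode: descendant sets + branch lengths for length-weighted sampling
  bool record_desc;
  std::vector<std::vector<int>>* desc_store;
  std::vector<double>* branch_len;    // parallel to closed_desc
  std::vector<int>* branch_desc;      // index into desc_store
};

// Simulate one genealogy; lineages start at time 0 with the given demes and
// class counts.  Returns nothing; results flow through the recorders.
static void simulate_one(const std::vector<Epoch>& ep, int merge_epoch,
                         std::vector<Lineage>& lin, SimRecorders& rec) {
  int nE = (int) ep.size();
  int k = (int) lin.size();
  if (k < 2) stop("need at least 2 lineages");
  int kw = 0;
  for (int i = 0; i < k; ++i) if (lin[i].deme == 0) ++kw;
  int ke = k - kw;
  double t = 0.0;
  int e = 0;
  int next_node = 0;
  if (rec.record_tree) {
    // tips occupy node ids 0..k-1 already assigned by caller
    for (size_t i = 0; i < lin.size(); ++i)
      if (lin[i].node >= next_node) next_node = lin[i].node + 1;
  }
  if (e == merge_epoch) {  // merge at time 0: single ancestral deme
    for (int i = 0; i < k; ++i) lin[i].deme = 0;
    kw = k; ke = 0;
  }

  auto close_branch = [&](int idx, double now, int parent_node) {
    double len = now - lin[idx].birth;
    (*rec.totals)[lin[idx].ci + lin[idx].cj * rec.nw1] += len;
    *rec.sum_len += len;
    if (rec.record_tree) {
      rec.edge_child->push_back(lin[idx].node);
      rec.edge_parent->push_back(parent_node);
      rec.edge_len->push_back(len);
      rec.edge_ci->push_back(lin[idx].ci);
      rec.edge_cj->push_back(lin[idx].cj);
    }
    if (rec.record_desc) {
      rec.branch_len->push_back(len);
      rec.branch_desc->push_back(lin[idx].desc);
    }
  };

  while (k > 1) {
    const Epoch& E = ep[e];
    double tb = (e + 1 < nE) ? ep[e + 1].start : R_PosInf;
    double lam_cw, lam_ce, lam_mig, lam_tot;
    if (E.collapsed) {
      lam_cw = 0.5 * k * (k - 1) * E.lam_pair;
      lam_ce = 0.0;
      lam_mig = 0.0;
    } else {
      lam_cw = 0.25 * kw * (kw - 1) / E.Nw;
      lam_ce = (ke > 1) ? 0.25 * ke * (ke - 1) / E.Ne : 0.0;
      lam_mig = kw * E.mw + ke * E.me;
    }
    lam_tot = lam_cw + lam_ce + lam_mig;

    double dt = (lam_tot > 0.0) ? exp_rand() / lam_tot : R_PosInf;
    if (t + dt >= tb) {
      // advance to the epoch boundary; redraw clocks there
      if (!R_finite(tb))
        stop("model never coalesces: zero total rate in the final epoch");
      t = tb;
      if (E.collapsed) {
        // leaving a strong-migration epoch: locations are at stationarity
        kw = 0;
        for (int i = 0; i < k; ++i) {
          lin[i].deme = (unif_rand() < E.pi_w) ? 0 : 1;
          if (lin[i].deme == 0) ++kw;
        }
        ke = k - kw;
      }
      ++e;
      if (e == merge_epoch) {
        for (int i = 0; i < k; ++i) lin[i].deme = 0;
        kw = k; ke = 0;
      }
      continue;
    }
    t += dt;
    double u = unif_rand() * lam_tot;
    if (u < lam_cw + lam_ce) {
      // coalescence: pick a uniform pair within the chosen deme (or the
      // pooled set when collapsed)
      int deme_pick = (E.collapsed) ? -1 : ((u < lam_cw) ? 0 : 1);
      int kk = (deme_pick < 0) ? k : ((deme_pick == 0) ? kw : ke);
      // sample two distinct ranks among the kk eligible lineages
      int r1 = (int) (unif_rand() * kk); if (r1 >= kk) r1 = kk - 1;
      int r2 = (int) (unif_rand() * (kk - 1)); if (r2 >= kk - 1) r2 = kk - 2;
      if (r2 >= r1) ++r2;
      int i1 = -1, i2 = -1, seen = 0;
      for (int i = 0; i < k; ++i) {
        if (deme_pick >= 0 && lin[i].deme != deme_pick) continue;
        if (seen == r1) i1 = i;
        if (seen == r2) i2 = i;
        ++seen;
      }
      int parent_node = rec.record_tree ? next_node++ : -1;
      if (rec.record_tree) rec.node_time->push_back(t);
      close_branch(i1, t, parent_node);
      close_branch(i2, t, parent_node);
      // merge i2 into i1
      lin[i1].ci += lin[i2].ci;
      lin[i1].cj += lin[i2].cj;
      lin[i1].birth = t;
      if (rec.record_tree) lin[i1].node = parent_node;
      if (rec.record_desc) {
        std::vector<int>& a = (*rec.desc_store)[lin[i1].desc];
        std::vector<int>& b = (*rec.desc_store)[lin[i2].desc];
        a.insert(a.end(), b.begin(), b.end());
      }
      if (!E.collapsed) {
        if (lin[i1].deme == 0) --kw; else --ke;  // one fewer in that deme
      } else {
        --kw;  // bookkeeping only; recomputed at epoch exit
      }
      lin[i2] = lin[k - 1];
      lin.pop_back();
      --k;
      if (E.collapsed) { kw = k; ke = 0; }
    } else {
      // migration: move one uniform lineage of the source deme
      double v = u - lam_cw - lam_ce;
      int src = (v < kw * E.mw) ? 0 : 1;
      int kk = (src == 0) ? kw : ke;
      int r = (int) (unif_rand() * kk); if (r >= kk) r = kk - 1;
      int seen = 0;
      for (int i = 0; i < k; ++i) {
        if (lin[i].deme != src) continue;
        if (seen == r) {
          lin[i].deme = 1 - src;
          if (src == 0) { --kw; ++ke; } else { ++kw; --ke; }
          break;
        }
        ++seen;
      }
    }
  }
}

static std::vector<Lineage> init_lineages(int n_west, int n_east,
                                          bool tree, bool desc,
                                          std::vector<std::vector<int>>* store) {
  std::vector<Lineage> lin;
  lin.reserve(n_west + n_east);
  for (int i = 0; i < n_west + n_east; ++i) {
    Lineage L;
    L.deme = (i < n_west) ? 0 : 1;
    L.ci = (i < n_west) ? 1 : 0;
    L.cj = (i < n_west) ? 0 : 1;
    L.birth = 0.0;
    L.node = tree ? i : -1;
    L.desc = -1;
    if (desc) {
      store->push_back(std::vector<int>{i});
      L.desc = (int) store->size() - 1;
    }
    lin.push_back(L);
  }
  return lin;
}

//' @noRd
// [[Rcpp::export]]
List cpp_accumulate_jsfs(NumericVector starts, NumericVector Nw,
                         NumericVector Ne, NumericVector mw, NumericVector me,
                         int merge_epoch, int n_west, int n_east, int n_sims) {
  std::vector<Epoch> ep = prepare_epochs(starts, Nw, Ne, mw, me, merge_epoch);
  int nw1 = n_west + 1, ne1 = n_east + 1;
  std::vector<double> totals((size_t) nw1 * ne1, 0.0);
  double sum_len = 0.0;
  SimRecorders rec;
  rec.totals = &totals; rec.sum_len = &sum_len; rec.nw1 = nw1;
  rec.record_tree = false; rec.record_desc = false;
  for (int s = 0; s < n_sims; ++s) {
    std::vector<Lineage> lin = init_lineages(n_west, n_east, false, false, nullptr);
    simulate_one(ep, merge_epoch, lin, rec);
  }
  NumericMatrix M(nw1, ne1);
  for (int j = 0; j < ne1; ++j)
    for (int i = 0; i < nw1; ++i)
      M(i, j) = totals[i + (size_t) j * nw1];
  return List::create(_["totals"] = M, _["sum_length"] = sum_len,
                      _["n_sims"] = n_sims);
}

//' @noRd
// [[Rcpp::export]]
List cpp_simulate_genealogy(NumericVector starts, NumericVector Nw,
                            NumericVector Ne, NumericVector mw,
                            NumericVector me, int merge_epoch,
                            int n_west, int n_east) {
  std::vector<Epoch> ep = prepare_epochs(starts, Nw, Ne, mw, me, merge_epoch);
  int n = n_west + n_east;
  int nw1 = n_west + 1, ne1 = n_east + 1;
  std::vector<double> totals((size_t) nw1 * ne1, 0.0);
  double sum_len = 0.0;
  std::vector<double> node_time;
  std::vector<int> edge_child, edge_parent, edge_ci, edge_cj;
  std::vector<double> edge_len;
  SimRecorders rec;
  rec.totals = &totals; rec.sum_len = &sum_len; rec.nw1 = nw1;
  rec.record_tree = true;
  rec.node_time = &node_time;
  rec.edge_child = &edge_child; rec.edge_parent = &edge_parent;
  rec.edge_len = &edge_len; rec.edge_ci = &edge_ci; rec.edge_cj = &edge_cj;
  rec.record_desc = false;
  std::vector<Lineage> lin = init_lineages(n_west, n_east, true, false, nullptr);
  simulate_one(ep, merge_epoch, lin, rec);
  return List::create(
      _["n_tips"] = n,
      _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
      _["edge_child"] = IntegerVector(edge_child.begin(), edge_child.end()),
      _["edge_parent"] = IntegerVector(edge_parent.begin(), edge_parent.end()),
      _["edge_length"] = NumericVector(edge_len.begin(), edge_len.end()),
      _["edge_i"] = IntegerVector(edge_ci.begin(), edge_ci.end()),
      _["edge_j"] = IntegerVector(edge_cj.begin(), edge_cj.end()),
      _["total_length"] = sum_len);
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_sim_loci(NumericVector starts, NumericVector Nw,
                           NumericVector Ne, NumericVector mw,
                           NumericVector me, int merge_epoch,
                           IntegerMatrix deme_assign) {
  // deme_assign: haplotypes x loci matrix of 0 (west) / 1 (east).
  // Returns haplotypes x loci derived-allele indicator matrix: one mutation
  // per locus placed on a branch chosen proportionally to its length
  // (infinite-sites: equivalent to sampling one SNP uniformly among the
  // locus's segregating sites).
  int n = deme_assign.nrow();
  int n_loci = deme_assign.ncol();
  std::vector<Epoch> ep = prepare_epochs(starts, Nw, Ne, mw, me, merge_epoch);
  IntegerMatrix out(n, n_loci);
  std::vector<double> totals((size_t) (n + 1) * (n + 1), 0.0);
  for (int l = 0; l < n_loci; ++l) {
    double sum_len = 0.0;
    std::vector<std::vector<int>> store;
    std::vector<double> blen;
    std::vector<int> bdesc;
    store.reserve(2 * n);
    SimRecorders rec;
    rec.totals = &totals; rec.sum_len = &sum_len; rec.nw1 = n + 1;
    rec.record_tree = false;
    rec.record_desc = true;
    rec.desc_store = &store; rec.branch_len = &blen; rec.branch_desc = &bdesc;
    std::vector<Lineage> lin;
    lin.reserve(n);
    for (int i = 0; i < n; ++i) {
      Lineage L;
      L.deme = deme_assign(i, l);
      L.ci = (L.deme == 0) ? 1 : 0;
      L.cj = (L.deme == 0) ? 0 : 1;
      L.birth = 0.0; L.node = -1;
      store.push_back(std::vector<int>{i});
      L.desc = i;
      lin.push_back(L);
    }
    simulate_one(ep, merge_epoch, lin, rec);
    // length-weighted branch choice
    double u = unif_rand() * sum_len, acc = 0.0;
    int pick = (int) blen.size() - 1;
    for (size_t b = 0; b < blen.size(); ++b) {
      acc += blen[b];
      if (u <= acc) { pick = (int) b; break; }
    }
    const std::vector<int>& d = store[bdesc[pick]];
    for (size_t q = 0; q < d.size(); ++q) out(d[q], l) = 1;
  }
  return out;
}
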