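// Simulation core: lattice sprout with VEGF/Dll4/Notch lateral inhibition,
// actin-limited filopodia chains and Cellular-Potts rearrangement.
// All stochasticity flows from one mt19937_64 stream per run, so a (config,
// seed) pair reproduces bit-identical trajectories.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double u01(std::mt19937_64 &gen) {
  return (gen() >> 11) * (1.0 / 9007199254740992.0);
}

struct Params {
  // signalling
  double V_max, K_sat, V0, g, m, delta_D, D_max, sigma, rho_D, rho_R, R_floor;
  int tau, W;
  double theta_D, theta_V;
  bool dapt;
  double su_fold;
  // filopodia
  int A_max, L_max;
  double C_act, p_ret, v_ret, fil_over;
  // adhesion
  double eta, alpha_strong, alpha_weak;
  // potts
  double lambda_mig, N_ref, notch_cap, cor_lat, cor_back, T, lambda_A, J0,
      J_cm, gamma, beta_fil;
  int n_attempts, stabilization, min_area, spread_slack;
  bool movement, filopodia_on;
  int total_timesteps, record_from;
  double init_spread;
};

static Params read_params(const List &par) {
  Params p;
  p.V_max = par["V_max"]; p.K_sat = par["K_sat"]; p.V0 = par["V0"];
  p.g = par["g"]; p.m = par["m"]; p.delta_D = par["delta_D"];
  p.D_max = par["D_max"]; p.sigma = par["sigma"];
  p.rho_D = par["rho_D"]; p.rho_R = par["rho_R"];
  p.R_floor = par["R_floor"];
  p.tau = par["tau"]; p.W = par["W"];
  p.theta_D = par["theta_D"]; p.theta_V = par["theta_V"];
  p.dapt = as<bool>(par["dapt"]); p.su_fold = par["su_fold"];
  p.A_max = par["A_max"]; p.L_max = par["L_max"];
  p.C_act = par["C"]; p.p_ret = par["p_ret"]; p.v_ret = par["v_ret"];
  p.fil_over = par["fil_over"];
  p.eta = par["eta"];
  p.alpha_strong = par["alpha_strong"]; p.alpha_weak = par["alpha_weak"];
  p.lambda_mig = par["lambda_mig"]; p.N_ref = par["N_ref"];
  p.notch_cap = par["notch_cap"];
  p.cor_lat = par["cor_lat"]; p.cor_back = par["cor_back"];
  p.T = par["T"];
  p.lambda_A = par["lambda_A"]; p.J0 = par["J0"]; p.J_cm = par["J_cm"];
  p.gamma = par["gamma"]; p.beta_fil = par["beta_fil"];
  p.n_attempts = par["n_attempts"]; p.stabilization = par["stabilization"];
  p.min_area = par["min_area"];
  p.spread_slack = par["spread_slack"];
  p.movement = as<bool>(par["movement"]);
  p.filopodia_on = as<bool>(par["filopodia_on"]);
  p.total_timesteps = par["total_timesteps"];
  p.record_from = par["record_from"];
  p.init_spread = par["init_spread"];
  return p;
}

static inline double site_sat(int x, const Params &p) {
  double v = p.m * (p.V0 + p.g * x);
  if (v < 0) v = 0;
  v /= (p.K_sat * p.su_fold);
  return v > 1 ? 1.0 : v;
}

// Contact energy between two owners with cortex tension folded in
// (gamma per cell endpoint of a heterotypic edge).
static inline double contact_e(int o1, int o2, const std::vector<double> &alpha,
                               const Params &p) {
  if (o1 == o2) return 0.0;
  if (o1 == 0 || o2 == 0) return p.J_cm + p.gamma;
  return p.J0 - alpha[o1 - 1] - alpha[o2 - 1] + 2.0 * p.gamma;
}

// Local energy change of copying owner `src` onto site b (row rb, col cb).
static double delta_h_local(const int *owner, int L, int C, int rb, int cb,
                            int src, int tgt, const std::vector<double> &alpha,
                            const Params &p, const std::vector<int> &areas,
                            int target_area) {
  double dH = 0.0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};
  for (int k = 0; k < 4; ++k) {
    int r = rb + dr[k];
    int c = (cb + dc[k] + C) % C;
    if (r < 0 || r >= L) continue;
    int o = owner[r + L * c];
    dH += contact_e(src, o, alpha, p) - contact_e(tgt, o, alpha, p);
  }
  if (tgt > 0) {
    double at = areas[tgt - 1];
    dH += p.lambda_A * ((at - 1 - target_area) * (at - 1 - target_area) -
                        (at - target_area) * (at - target_area));
  }
  if (src > 0) {
    double as = areas[src - 1];
    dH += p.lambda_A * ((as + 1 - target_area) * (as + 1 - target_area) -
                        (as - target_area) * (as - target_area));
  }
  return dH;
}

// Exact check: is the territory of `tgt` still 4-connected (with
// circumferential wrap) after removing site b? BFS over the territory.
static bool connected_without(const int *owner, int L, int C, int rb, int cb,
                              int tgt, int area) {
  int start = -1;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};
  for (int k = 0; k < 4 && start < 0; ++k) {
    int r = rb + dr[k];
    int c = (cb + dc[k] + C) % C;
    if (r >= 0 && r < L && owner[r + L * c] == tgt) start = r + L * c;
  }
  if (start < 0) return false;
  std::vector<int> stack;
  std::vector<char> seen(L * C, 0);
  stack.push_back(start);
  seen[start] = 1;
  seen[rb + L * cb] = 1;  // removed site blocks paths
  int reached = 1;
  while (!stack.empty()) {
    int s = stack.back();
    stack.pop_back();
    int r = s % L, c = s / L;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k];
      int cc = (c + dc[k] + C) % C;
      if (rr < 0 || rr >= L) continue;
      int q = rr + L * cc;
      if (!seen[q] && owner[q] == tgt) {
        seen[q] = 1;
        ++reached;
        stack.push_back(q);
      }
    }
  }
  return reached == area - 1;
}

// Local (Moore-neighbourhood) connectivity guard: conservative test that the
// 4-neighbours of b belonging to `tgt` stay connected when b is removed.
static bool stays_connected(const int *owner, int L, int C, int rb, int cb,
                            int tgt) {
  // ring positions clockwise; odd indices are the 4-neighbours
  const int dr[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const int dc[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  bool isq[8];
  for (int i = 0; i < 8; ++i) {
    int r = rb + dr[i];
    int c = (cb + dc[i] + C) % C;
    isq[i] = (r >= 0 && r < L) && owner[r + L * c] == tgt;
  }
  // count cyclic runs of q-sites that contain at least one 4-neighbour
  int runs_with_edge = 0;
  int start = -1;
  for (int i = 0; i < 8; ++i) if (!isq[i]) { start = i; break; }
  if (start < 0) return true;  // full ring of q
  bool in_run = false, run_has_edge = false;
  for (int k = 1; k <= 8; ++k) {
    int i = (start + k) % 8;
    if (isq[i]) {
      in_run = true;
      if (i % 2 == 1) run_has_edge = true;
    } else if (in_run) {
      if (run_has_edge) ++runs_with_edge;
      in_run = false;
      run_has_edge = false;
    }
  }
  return runs_with_edge <= 1;
}

// [[Rcpp::export]]
NumericVector rng_uniforms_cpp(int n, int seed) {
  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u01(gen);
  return out;
}

// [[Rcpp::export]]
int metropolis_accept_cpp(double dH, double T, int n, int seed) {
  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  double p = dH <= 0 ? 1.0 : std::exp(-dH / T);
  int acc = 0;
  for (int i = 0; i < n; ++i) if (u01(gen) < p) ++acc;
  return acc;
}

// [[Rcpp::export]]
List delta_h_cpp(IntegerMatrix owner, IntegerVector a, IntegerVector b,
                 NumericVector alpha_cells, List potts, int target_area,
                 int min_area) {
  Params p{};
  p.lambda_A = potts["lambda_A"]; p.J0 = potts["J0"]; p.J_cm = potts["J_cm"];
  p.gamma = potts["gamma"];
  int L = owner.nrow(), C = owner.ncol();
  std::vector<double> alpha(alpha_cells.begin(), alpha_cells.end());
  int n_cells = alpha.size();
  std::vector<int> areas(n_cells, 0);
  const int *own = owner.begin();
  for (int i = 0; i < L * C; ++i) if (own[i] > 0) areas[own[i] - 1]++;
  int ra = a[0], ca = a[1], rb = b[0], cb = b[1];  // 0-based x,y
  int src = own[ra + L * ca], tgt = own[rb + L * cb];
  if (src == tgt) return List::create(_["dH"] = 0.0, _["valid"] = true);
  if (tgt > 0) {
    if (areas[tgt - 1] <= min_area ||
        (!stays_connected(own, L, C, rb, cb, tgt) &&
         !connected_without(own, L, C, rb, cb, tgt, areas[tgt - 1]))) {
      return List::create(_["dH"] = NA_REAL, _["valid"] = false);
    }
  }
  double dH = delta_h_local(own, L, C, rb, cb, src, tgt, alpha, p, areas,
                            target_area);
  return List::create(_["dH"] = dH, _["valid"] = true);
}

// [[Rcpp::export]]
List run_sprout_cpp(IntegerMatrix owner0, IntegerVector genotype,
                    NumericVector k_fil, NumericVector k_cor,
                    NumericVector k_adh, List par, int target_area, int seed) {
  Params p = read_params(par);
  const int L = owner0.nrow(), C = owner0.ncol();
  const int n = genotype.size();
  std::vector<int> owner(owner0.begin(), owner0.begin() + L * C);
  std::mt19937_64 gen(static_cast<uint64_t>(seed));

  // initial receptor heterogeneity (same draws as seeded_uniforms in R)
  std::vector<double> R0(n);
  for (int c = 0; c < n; ++c) {
    double u = u01(gen);
    double r = p.V_max * (1.0 - p.init_spread + 2.0 * p.init_spread * u);
    R0[c] = std::min(p.V_max, std::max(0.0, r));
  }

  std::vector<int> areas(n, 0);
  int xmax = 0;
  for (int i = 0; i < L * C; ++i) {
    if (owner[i] > 0) {
      areas[owner[i] - 1]++;
      int x = i % L;
      if (x > xmax) xmax = x;
    }
  }

  // filopodia: at most one chain per circumferential column
  std::vector<int> ch_cell(C, 0), ch_lo(C, 0), ch_hi(C, -1);
  std::vector<int> deployed(n, 0);

  // signalling state
  std::vector<double> Rlev(R0), Vp(n, 0), Dl(n, 0), Np(n, 0),
      Vhat(n, 0), Nhat(n, 0);
  std::vector<double> D_buf((size_t)p.tau * n, 0.0),
      R_buf((size_t)p.tau * n, 0.0);
  std::vector<double> Vp_hist((size_t)p.W * n, 0.0),
      Np_hist((size_t)p.W * n, 0.0);
  std::vector<double> Vp_sum(n, 0), Np_sum(n, 0);
  // accepted-move diagnostics: cell->cell, cell->medium, medium->cell,
  // proposals gated away, proposals rejected by Metropolis
  long acc_cc = 0, acc_cm = 0, acc_mc = 0, n_gated = 0, n_rej = 0;

  const int T_total = p.total_timesteps;
  const int rec0 = p.record_from;
  const int T_rec = std::max(0, T_total - rec0);
  const int n_pairs = n * (n - 1) / 2;
  NumericMatrix rec_comx(T_rec, n), rec_comy(T_rec, n), rec_vp(T_rec, n),
      rec_d(T_rec, n), rec_np(T_rec, n), rec_r(T_rec, n), rec_vhat(T_rec, n),
      rec_nhat(T_rec, n);
  IntegerMatrix rec_adh(T_rec, n), rec_act(T_rec, n), rec_actin(T_rec, n),
      rec_fcount(T_rec, n), rec_flen(T_rec, n);
  IntegerVector rec_tip(T_rec);
  LogicalMatrix rec_adj(T_rec, n_pairs);

  std::vector<double> sat_sum(n), adh_alpha(n);
  std::vector<int> mem_cnt(n);
  std::vector<double> jlen((size_t)n * n);
  std::vector<int> front_cnt(n);
  std::vector<double> comx_s(n), comy_sin(n), comy_cos(n);
  std::vector<int> com_cnt(n);
  const double two_pi_over_C = 2.0 * M_PI / C;

  for (int t = 0; t < T_total; ++t) {
    // ---- scan: boundary memAgents, junction lengths, areas sanity ----
    std::fill(sat_sum.begin(), sat_sum.end(), 0.0);
    std::fill(mem_cnt.begin(), mem_cnt.end(), 0);
    std::fill(jlen.begin(), jlen.end(), 0.0);
    int scan_hi = std::min(L - 1, xmax);
    for (int y = 0; y < C; ++y) {
      int yr = (y + 1) % C, yl = (y - 1 + C) % C;
      for (int x = 0; x <= scan_hi; ++x) {
        int o = owner[x + L * y];
        int orr = owner[x + L * yr];
        if (o > 0) {
          int up = x > 0 ? owner[x - 1 + L * y] : -1;
          int dn = x < L - 1 ? owner[x + 1 + L * y] : -1;
          int lf = owner[x + L * yl];
          if (up != o || dn != o || lf != o || orr != o) {
            mem_cnt[o - 1]++;
            sat_sum[o - 1] += site_sat(x, p);
          }
          if (dn > 0 && dn != o) {  // axial junction edge, counted once
            jlen[(o - 1) * n + (dn - 1)] += 1;
            jlen[(dn - 1) * n + (o - 1)] += 1;
          }
        }
        if (o > 0 && orr > 0 && o != orr) {  // circumferential edge
          jlen[(o - 1) * n + (orr - 1)] += 1;
          jlen[(orr - 1) * n + (o - 1)] += 1;
        }
      }
    }
    // chain validation: base support must still belong to the owning cell
    for (int y = 0; y < C; ++y) {
      if (ch_hi[y] < ch_lo[y] || ch_cell[y] == 0) continue;
      int cell = ch_cell[y];
      int base = ch_lo[y] - 1;
      if (base < 0 || owner[base + L * y] != cell) {
        deployed[cell - 1] -= ch_hi[y] - ch_lo[y] + 1;
        ch_cell[y] = 0; ch_hi[y] = -1; ch_lo[y] = 0;
        continue;
      }
      for (int x = ch_lo[y]; x <= ch_hi[y]; ++x) {
        mem_cnt[cell - 1]++;
        sat_sum[cell - 1] += site_sat(x, p);
      }
    }

    // ---- signalling update ----
    int slot = t % p.tau;
    for (int c = 0; c < n; ++c) {
      double target_D = t >= p.tau ? D_buf[(size_t)slot * n + c] : 0.0;
      double target_R = t >= p.tau ? R_buf[(size_t)slot * n + c] : R0[c];
      Dl[c] += p.rho_D * (target_D - Dl[c]);
      Rlev[c] += p.rho_R * (target_R - Rlev[c]);
    }
    for (int c = 0; c < n; ++c) {
      double sbar = mem_cnt[c] > 0 ? sat_sum[c] / mem_cnt[c] : 0.0;
      Vp[c] = Rlev[c] * sbar;
      double dprod = p.delta_D * Vp[c];
      D_buf[(size_t)slot * n + c] = dprod > p.D_max ? p.D_max : dprod;
    }
    for (int c = 0; c < n; ++c) {
      Np[c] = 0.0;
      if (!p.dapt) {
        double tot = 0.0;
        for (int j = 0; j < n; ++j) tot += jlen[(size_t)c * n + j];
        if (tot > 0) {
          for (int j = 0; j < n; ++j) {
            double lj = jlen[(size_t)c * n + j];
            if (lj > 0 && Dl[j] >= p.theta_D) Np[c] += Dl[j] * lj / tot;
          }
        }
      }
      double rnew = p.V_max - p.sigma * Np[c];
      if (rnew < p.R_floor) rnew = p.R_floor;
      if (rnew > p.V_max) rnew = p.V_max;
      R_buf[(size_t)slot * n + c] = rnew;
    }
    int wslot = t % p.W;
    int denom = std::min(t + 1, p.W);
    for (int c = 0; c < n; ++c) {
      Vp_sum[c] += Vp[c] - Vp_hist[(size_t)wslot * n + c];
      Np_sum[c] += Np[c] - Np_hist[(size_t)wslot * n + c];
      Vp_hist[(size_t)wslot * n + c] = Vp[c];
      Np_hist[(size_t)wslot * n + c] = Np[c];
      Vhat[c] = Vp_sum[c] / denom;
      Nhat[c] = Np_sum[c] / denom;
      adh_alpha[c] = (k_adh[c] * Vhat[c] >= p.eta) ? p.alpha_weak
                                                   : p.alpha_strong;
    }

    // ---- filopodia dynamics ----
    if (p.filopodia_on) {
      for (int y = 0; y < C; ++y) {
        if (ch_cell[y] > 0 && ch_hi[y] >= ch_lo[y]) {
          int cell = ch_cell[y];
          // tip retraction: spontaneous or low local activation
          double act = Rlev[cell - 1] * site_sat(ch_hi[y], p) / p.V_max;
          double u = u01(gen);
          if (u < p.p_ret || act < p.v_ret) {
            ch_hi[y]--;
            deployed[cell - 1]--;
            if (ch_hi[y] < ch_lo[y]) { ch_cell[y] = 0; ch_hi[y] = -1; }
          }
        }
        if (ch_cell[y] > 0 && ch_hi[y] >= ch_lo[y]) {
          // extend the existing chain from its tip; filopodia are not
          // volume-exclusive and may reach over neighbouring cell bodies
          int cell = ch_cell[y];
          int len = ch_hi[y] - ch_lo[y] + 1;
          int nx = ch_hi[y] + 1;
          if (len < p.L_max && nx < L && deployed[cell - 1] < p.A_max) {
            double pe = k_fil[cell - 1] * p.C_act * Rlev[cell - 1] *
                        site_sat(ch_hi[y], p) / p.V_max;
            // crawling over a neighbour's body is slower than free extension
            if (owner[nx + L * y] > 0) pe *= p.fil_over;
            if (pe > 1) pe = 1;
            if (u01(gen) < pe) {
              ch_hi[y] = nx;
              deployed[cell - 1]++;
            }
          }
        } else {
          // seed a new chain: front-edge sites of every cell stacked in
          // this column get a chance, front-most first; the first
          // successful polymerization claims the column
          int x_hi = std::min(L - 2, xmax);
          for (int x = x_hi; x >= 0; --x) {
            int o = owner[x + L * y];
            if (o <= 0) continue;
            if (owner[x + 1 + L * y] == o) continue;  // interior, not edge
            if (deployed[o - 1] >= p.A_max) continue;
            double pe = k_fil[o - 1] * p.C_act * Rlev[o - 1] *
                        site_sat(x, p) / p.V_max;
            if (owner[x + 1 + L * y] > 0) pe *= p.fil_over;
            if (pe > 1) pe = 1;
            if (u01(gen) < pe) {
              ch_cell[y] = o;
              ch_lo[y] = ch_hi[y] = x + 1;
              deployed[o - 1]++;
              break;
            }
          }
        }
      }
    }

    // ---- rearrangement (Cellular Potts, Metropolis) ----
    if (p.movement && t >= p.stabilization) {
      for (int att = 0; att < p.n_attempts; ++att) {
        int hi_row = std::min(L - 1, xmax + 1);
        int rb = (int)(u01(gen) * (hi_row + 1));
        if (rb > hi_row) rb = hi_row;
        int cb = (int)(u01(gen) * C);
        if (cb >= C) cb = C - 1;
        int dir = (int)(u01(gen) * 4);
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, 1, -1};
        int ra = rb + dr[dir];
        int ca = (cb + dc[dir] + C) % C;
        if (ra < 0 || ra >= L) continue;
        int src = owner[ra + L * ca];
        int tgt = owner[rb + L * cb];
        if (src == tgt) continue;
        bool own_filo = ch_cell[cb] == src && src > 0 &&
                        rb >= ch_lo[cb] && rb <= ch_hi[cb];
        if (src > 0) {
          // protrusive gate. All expansion is polarized up the VEGF
          // gradient (full drive frontward, reduced laterally, minimal
          // rearward). Tension homeostasis bypasses the Notch gate: a cell
          // squeezed well below its target area re-spreads passively, and
          // sites of a clearly over-target neighbour are yielded passively;
          // only expansion beyond the resting footprint against a resting
          // neighbour needs the Notch-gated protrusion machinery.
          // tension exemptions act on cell-cell boundaries only: breaching
          // into free medium always needs the protrusion machinery
          bool squeezed = tgt > 0 &&
                          areas[src - 1] < target_area - p.spread_slack;
          bool relieving = tgt > 0 &&
                           areas[tgt - 1] > target_area + p.spread_slack;
          if (!squeezed && !relieving) {
            // polarized up the gradient: full drive frontward, reduced
            // laterally, minimal rearward
            double pc = rb > ra ? 1.0 : (rb == ra ? p.cor_lat : p.cor_back);
            double nn = Nhat[src - 1] / p.N_ref;
            if (nn > p.notch_cap) nn = p.notch_cap;
            pc *= k_cor[src - 1] * p.lambda_mig * (1.0 - nn);
            if (pc > 1) pc = 1;
            if (u01(gen) >= pc) { ++n_gated; continue; }
          }
        }
        if (tgt > 0) {
          if (areas[tgt - 1] <= p.min_area) continue;
          // fast local screen; exact BFS fallback for the rare layouts the
          // conservative Moore test cannot certify
          if (!stays_connected(owner.data(), L, C, rb, cb, tgt) &&
              !connected_without(owner.data(), L, C, rb, cb, tgt,
                                 areas[tgt - 1])) {
            continue;
          }
        }
        double dH = delta_h_local(owner.data(), L, C, rb, cb, src, tgt,
                                  adh_alpha, p, areas, target_area);
        if (own_filo) dH -= p.beta_fil;
        double acc = dH <= 0 ? 1.0 : std::exp(-dH / p.T);
        if (u01(gen) >= acc) { ++n_rej; continue; }
        // apply
        if (src > 0 && tgt > 0) ++acc_cc;
        else if (src > 0) ++acc_cm;
        else ++acc_mc;
        owner[rb + L * cb] = src;
        if (tgt > 0) areas[tgt - 1]--;
        if (src > 0) {
          areas[src - 1]++;
          if (rb > xmax) xmax = rb;
        }
        // chain bookkeeping in this column
        if (ch_cell[cb] > 0) {
          int cc = ch_cell[cb];
          if (own_filo) {
            // body absorbed chain sites up to rb; remainder re-anchors
            int freed = rb - ch_lo[cb] + 1;
            deployed[cc - 1] -= freed;
            ch_lo[cb] = rb + 1;
            if (ch_hi[cb] < ch_lo[cb]) { ch_cell[cb] = 0; ch_hi[cb] = -1; }
          } else {
            int base = ch_lo[cb] - 1;
            if (base < 0 || owner[base + L * cb] != cc) {
              deployed[cc - 1] -= ch_hi[cb] - ch_lo[cb] + 1;
              ch_cell[cb] = 0; ch_hi[cb] = -1;
            }
          }
        }
      }
      // xmax may shrink after retractions; refresh lazily
      while (xmax > 0) {
        bool any = false;
        for (int y = 0; y < C; ++y) {
          if (owner[xmax + L * y] > 0) { any = true; break; }
        }
        if (any) break;
        --xmax;
      }
    }

    // ---- record ----
    if (t >= rec0) {
      int tr = t - rec0;
      std::fill(comx_s.begin(), comx_s.end(), 0.0);
      std::fill(comy_sin.begin(), comy_sin.end(), 0.0);
      std::fill(comy_cos.begin(), comy_cos.end(), 0.0);
      std::fill(com_cnt.begin(), com_cnt.end(), 0);
      std::fill(front_cnt.begin(), front_cnt.end(), 0);
      std::vector<bool> adj((size_t)n * n, false);
      int scan2 = std::min(L - 1, xmax);
      for (int y = 0; y < C; ++y) {
        int yr = (y + 1) % C, yl = (y - 1 + C) % C;
        for (int x = 0; x <= scan2; ++x) {
          int o = owner[x + L * y];
          int orr = owner[x + L * yr];
          if (o > 0) {
            int up = x > 0 ? owner[x - 1 + L * y] : -1;
            int dn = x < L - 1 ? owner[x + 1 + L * y] : -1;
            int lf = owner[x + L * yl];
            if (up != o || dn != o || lf != o || orr != o) {
              com_cnt[o - 1]++;
              comx_s[o - 1] += x;
              comy_sin[o - 1] += std::sin(two_pi_over_C * y);
              comy_cos[o - 1] += std::cos(two_pi_over_C * y);
            }
            if (dn > 0 && dn != o) {
              adj[(o - 1) * n + (dn - 1)] = adj[(dn - 1) * n + (o - 1)] = true;
            }
            if (x == xmax) front_cnt[o - 1]++;
          }
          if (o > 0 && orr > 0 && o != orr) {
            adj[(o - 1) * n + (orr - 1)] = adj[(orr - 1) * n + (o - 1)] = true;
          }
        }
      }
      // centre of mass is recorded over cell-body membrane sites only:
      // positions and overtakes follow the relative position of cell
      // bodies, not of transient cytoskeletal protrusions
      std::vector<int> fcount(n, 0), flen(n, 0);
      for (int y = 0; y < C; ++y) {
        if (ch_cell[y] > 0 && ch_hi[y] >= ch_lo[y]) {
          int cell = ch_cell[y];
          fcount[cell - 1]++;
          flen[cell - 1] += ch_hi[y] - ch_lo[y] + 1;
        }
      }
      // tip: most cell-body sites in the front row; tie -> higher Vp,
      // then lower id
      int tip = 0;
      for (int c = 1; c < n; ++c) {
        if (front_cnt[c] > front_cnt[tip] ||
            (front_cnt[c] == front_cnt[tip] && Vp[c] > Vp[tip])) {
          tip = c;
        }
      }
      rec_tip[tr] = tip + 1;
      for (int c = 0; c < n; ++c) {
        double my = 0.0;
        if (com_cnt[c] > 0) {
          my = std::atan2(comy_sin[c] / com_cnt[c], comy_cos[c] / com_cnt[c]) /
               two_pi_over_C;
          if (my < 0) my += C;
          rec_comx(tr, c) = comx_s[c] / com_cnt[c];
        } else {
          rec_comx(tr, c) = NA_REAL;
        }
        rec_comy(tr, c) = my;
        rec_vp(tr, c) = Vp[c];
        rec_d(tr, c) = Dl[c];
        rec_np(tr, c) = Np[c];
        rec_r(tr, c) = Rlev[c];
        rec_vhat(tr, c) = Vhat[c];
        rec_nhat(tr, c) = Nhat[c];
        rec_adh(tr, c) = adh_alpha[c] == p.alpha_weak ? 2 : 1;
        rec_act(tr, c) = (Dl[c] >= p.theta_D && Vp[c] >= p.theta_V) ? 1 : 0;
        rec_actin(tr, c) = deployed[c];
        rec_fcount(tr, c) = fcount[c];
        rec_flen(tr, c) = flen[c];
      }
      int k = 0;
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          rec_adj(tr, k++) = adj[(size_t)i * n + j];
        }
      }
    }
  }

  IntegerMatrix owner_out(L, C);
  std::copy(owner.begin(), owner.end(), owner_out.begin());
  return List::create(
      _["com_x"] = rec_comx, _["com_y"] = rec_comy, _["Vp"] = rec_vp,
      _["D"] = rec_d, _["Np"] = rec_np, _["R"] = rec_r, _["Vhat"] = rec_vhat,
      _["Nhat"] = rec_nhat, _["adhesion"] = rec_adh, _["active"] = rec_act,
      _["actin"] = rec_actin, _["filo_count"] = rec_fcount,
      _["filo_len"] = rec_flen, _["tip"] = rec_tip, _["adjacency"] = rec_adj,
      _["owner_final"] = owner_out,
      _["chain_cell"] = IntegerVector(ch_cell.begin(), ch_cell.end()),
      _["chain_lo"] = IntegerVector(ch_lo.begin(), ch_lo.end()),
      _["chain_hi"] = IntegerVector(ch_hi.begin(), ch_hi.end()),
      _["R_final"] = NumericVector(Rlev.begin(), Rlev.end()),
      _["areas"] = IntegerVector(areas.begin(), areas.end()),
      _["move_stats"] = NumericVector::create(
          _["cell_cell"] = (double)acc_cc, _["cell_medium"] = (double)acc_cm,
          _["medium_cell"] = (double)acc_mc, _["gated"] = (double)n_gated,
          _["rejected"] = (double)n_rej));
}
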