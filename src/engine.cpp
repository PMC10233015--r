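// Time-stepped integration of the cone-pathway network.
//
// Graded cells (photoreceptors, horizontal, bipolar, amacrine) are leaky
// integrators advanced by forward Euler (their time constants are >= 8 ms,
// far above the default 0.025 ms step).  RGC somas carry the seven-channel
// Hodgkin-Huxley dynamics and are advanced with exponential (Rush-Larsen)
// updates for both gates and voltage, which stays stable through the very
// large sodium conductance at spike peak.  Graded synaptic pooling and the
// per-projection delay buffers are evaluated on a coarser synaptic-update
// grid (default 0.25 ms): every presynaptic cell is graded, so its voltage
// moves slowly compared with that grid.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SigTable {
  // conductance lookup over presynaptic voltage
  std::vector<double> g;
  double v_lo, inv_step;
  int n;
  double operator()(double v) const {
    double u = (v - v_lo) * inv_step;
    if (u <= 0) return g[0];
    if (u >= n - 1) return g[n - 1];
    int i = (int)u;
    double f = u - i;
    return g[i] * (1 - f) + g[i + 1] * f;
  }
};

struct Projection {
  int pre_type;
  int delay;                  // in synaptic-update intervals
  double Esyn;
  std::vector<int> post;      // global cell indices
  std::vector<int> ptr;       // CSR offsets, length post.size() + 1
  std::vector<int> pre_local; // index into presynaptic type's local array
  std::vector<double> w;
  SigTable tab;
};

inline void check_gate(double &x) {
  if (x < 0) x = 0; else if (x > 1) x = 1;
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(List net, List light, List elec, List cfg) {
  // --- unpack network ------------------------------------------------------
  IntegerVector type_idx = net["type_idx"];     // 0..8
  IntegerVector model = net["model"];           // 0 leaky, 1 PR, 2 RGC
  NumericVector Cm = net["Cm"], Gm = net["Gm"], Erest = net["Erest"];
  NumericVector Glight = net["Glight"], ext_gain = net["ext_gain"];
  NumericVector i_const = net["i_const"];
  IntegerVector rgc_class = net["rgc_class"];   // -1 / 0 / 1
  NumericVector v0_state = clone(as<NumericVector>(net["v_init"]));
  NumericMatrix rgc_g = net["rgc_g"];           // 2 x 7: Na,Ca,K,KA,KCa,h,CaT (nS)
  NumericMatrix rgc_e = net["rgc_e"];           // 2 x 3: ENa, EK, Eh
  List ca = net["ca"];
  const double ca_k_in = ca["k_in"], ca_tau = ca["tau"],
               ca_rest = ca["ca_rest"], ca_diss = ca["ca_diss"],
               ca_out = ca["ca_out"], rt_2f = ca["rt_2f"];
  NumericMatrix rates = net["rate_table"];      // 20 cols: alpha,beta x 10
  NumericVector rate_v = net["rate_v"];
  const double e_light = net["E_light"];

  const int n_cells = type_idx.size();
  const int n_types = 9;

  // --- config --------------------------------------------------------------
  const double dt = cfg["dt"];
  const int n_steps = cfg["n_steps"];
  const int stride = cfg["syn_stride"];
  const double spike_v = cfg["spike_v"];
  const int lockout = std::max(1, (int)std::round(
      as<double>(cfg["lockout_ms"]) / dt));
  IntegerVector trace_cells = cfg["trace_cells"]; // 0-based global, may be empty
  const int trace_stride = cfg["trace_stride"];

  // --- per-type member lists ----------------------------------------------
  std::vector<std::vector<int>> members(n_types);
  std::vector<int> local_idx(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    local_idx[i] = (int)members[type_idx[i]].size();
    members[type_idx[i]].push_back(i);
  }

  // --- projections ---------------------------------------------------------
  List plist = net["projections"];
  std::vector<Projection> proj(plist.size());
  std::vector<int> ring_len(n_types, 0);
  const double v_lo_tab = -120, v_step_tab = 0.1;
  const int n_tab = (int)std::round((60 - v_lo_tab) / v_step_tab) + 1;
  for (int k = 0; k < plist.size(); ++k) {
    List p = plist[k];
    Projection &P = proj[k];
    P.pre_type = as<int>(p["pre_type"]);
    double delay_ms = as<double>(p["tau"]);
    P.delay = std::max(1, (int)std::round(delay_ms / (dt * stride)));
    P.Esyn = as<double>(p["E_syn"]);
    P.post = as<std::vector<int>>(p["post"]);
    P.ptr = as<std::vector<int>>(p["ptr"]);
    P.pre_local = as<std::vector<int>>(p["pre_local"]);
    P.w = as<std::vector<double>>(p["w"]);
    double gmin = as<double>(p["G_min"]), gmax = as<double>(p["G_max"]);
    double v50 = as<double>(p["V50"]), beta = as<double>(p["beta"]);
    bool inc = as<std::string>(p["kind"]) == "I";
    P.tab.v_lo = v_lo_tab; P.tab.inv_step = 1.0 / v_step_tab; P.tab.n = n_tab;
    P.tab.g.resize(n_tab);
    for (int i = 0; i < n_tab; ++i) {
      double v = v_lo_tab + i * v_step_tab;
      double s = 1.0 / (1.0 + std::exp((v - v50) / beta)); // decreasing
      if (inc) s = 1.0 - s;
      P.tab.g[i] = gmin + (gmax - gmin) * s;
    }
    ring_len[P.pre_type] = std::max(ring_len[P.pre_type], P.delay + 1);
  }

  // --- delay rings (per presynaptic type, at synaptic-update resolution) ---
  std::vector<std::vector<double>> ring(n_types);
  for (int ty = 0; ty < n_types; ++ty)
    if (ring_len[ty] > 0)
      ring[ty].assign((size_t)ring_len[ty] * members[ty].size(), 0.0);
  std::vector<double> v(v0_state.begin(), v0_state.end());
  for (int ty = 0; ty < n_types; ++ty)
    for (int s = 0; s < ring_len[ty]; ++s)
      for (size_t j = 0; j < members[ty].size(); ++j)
        ring[ty][(size_t)s * members[ty].size() + j] = v[members[ty][j]];

  // --- RGC gating tables (Rush-Larsen factors precomputed for this dt) -----
  const int n_rv = rate_v.size();
  const double rv_lo = rate_v[0];
  const double rv_step = rate_v[1] - rate_v[0];
  // 8 first-order gates: m h c n mA hA nh mT -> columns 0..15 (alpha,beta)
  // hT (16,17) and dT (18,19) integrate forward Euler from alpha/beta.
  std::vector<double> xinf(8 * n_rv), efac(8 * n_rv);
  for (int g = 0; g < 8; ++g)
    for (int i = 0; i < n_rv; ++i) {
      double a = rates(i, 2 * g), b = rates(i, 2 * g + 1);
      xinf[g * n_rv + i] = a / (a + b);
      efac[g * n_rv + i] = std::exp(-dt * (a + b));
    }
  std::vector<double> aT(2 * n_rv), bT(2 * n_rv);
  for (int g = 0; g < 2; ++g)
    for (int i = 0; i < n_rv; ++i) {
      aT[g * n_rv + i] = rates(i, 16 + 2 * g);
      bT[g * n_rv + i] = rates(i, 16 + 2 * g + 1);
    }
  auto rate_at = [&](const std::vector<double> &tab, int g, double vv) {
    double u = (vv - rv_lo) / rv_step;
    if (u <= 0) return tab[g * n_rv];
    if (u >= n_rv - 1) return tab[g * n_rv + n_rv - 1];
    int i = (int)u; double f = u - i;
    return tab[g * n_rv + i] * (1 - f) + tab[g * n_rv + i + 1] * f;
  };

  // --- RGC state -----------------------------------------------------------
  std::vector<int> rgc_cells;
  for (int i = 0; i < n_cells; ++i) if (model[i] == 2) rgc_cells.push_back(i);
  const int n_rgc = (int)rgc_cells.size();
  std::vector<int> rgc_slot(n_cells, -1);
  for (int r = 0; r < n_rgc; ++r) rgc_slot[rgc_cells[r]] = r;
  // gates: m h c n mA hA nh mT hT dT + Ca
  std::vector<double> gate(10 * n_rgc), ca_i(n_rgc, ca_rest);
  for (int r = 0; r < n_rgc; ++r) {
    double vv = v[rgc_cells[r]];
    for (int g = 0; g < 8; ++g)
      gate[10 * r + g] = rate_at(xinf, g, vv);
    double rh = rate_at(aT, 0, vv) / rate_at(bT, 0, vv);
    double rd = rate_at(aT, 1, vv) / rate_at(bT, 1, vv);
    double z = 1.0 / (1.0 + rh + rd);
    gate[10 * r + 8] = rh * z;
    gate[10 * r + 9] = rd * z;
  }
  std::vector<int> last_spike(n_rgc, -1000000);

  // --- stimuli -------------------------------------------------------------
  IntegerVector pr_cells = light["pr_cells"];    // 0-based global indices
  NumericMatrix L = light["L"];                  // n_pr x n_seg
  NumericVector l_breaks = light["breaks"];      // n_seg + 1 boundaries (ms)
  std::vector<int> pr_row(n_cells, -1);
  for (int j = 0; j < pr_cells.size(); ++j) pr_row[pr_cells[j]] = j;
  NumericVector e_breaks = elec["breaks"];
  NumericVector e_val = elec["v0"];              // mV per segment

  // --- recording -----------------------------------------------------------
  std::vector<int> spike_cell;
  std::vector<double> spike_t;
  int n_trace_t = trace_cells.size() > 0 ?
      (n_steps + trace_stride - 1) / trace_stride : 0;
  NumericMatrix traces(trace_cells.size(), std::max(n_trace_t, 0));
  std::vector<double> trace_times(std::max(n_trace_t, 0));

  // --- accumulators --------------------------------------------------------
  std::vector<double> g_sum(n_cells, 0.0), gE_sum(n_cells, 0.0);
  std::vector<double> g_pre_buf;
  int l_seg = 0, e_seg = 0, syn_slot = 0, trace_col = 0;

  for (int t = 0; t < n_steps; ++t) {
    double now = t * dt;
    while (l_seg + 1 < l_breaks.size() - 1 && now >= l_breaks[l_seg + 1])
      ++l_seg;
    double v0_now = 0.0;
    if (e_val.size() > 0) {
      while (e_seg + 1 < e_breaks.size() - 1 && now >= e_breaks[e_seg + 1])
        ++e_seg;
      v0_now = e_val[e_seg];
    }

    if (t % stride == 0) {
      // write current voltages into the delay rings, then rebuild pooling
      for (int ty = 0; ty < n_types; ++ty)
        if (ring_len[ty] > 0) {
          size_t nt = members[ty].size();
          double *slot = &ring[ty][(size_t)(syn_slot % ring_len[ty]) * nt];
          for (size_t j = 0; j < nt; ++j) slot[j] = v[members[ty][j]];
        }
      std::fill(g_sum.begin(), g_sum.end(), 0.0);
      std::fill(gE_sum.begin(), gE_sum.end(), 0.0);
      for (auto &P : proj) {
        size_t nt = members[P.pre_type].size();
        int rl = ring_len[P.pre_type];
        int slot = ((syn_slot - P.delay) % rl + rl) % rl;
        const double *vd = &ring[P.pre_type][(size_t)slot * nt];
        g_pre_buf.resize(nt);
        for (size_t j = 0; j < nt; ++j) g_pre_buf[j] = P.tab(vd[j]);
        const int n_post = (int)P.post.size();
        for (int i = 0; i < n_post; ++i) {
          double acc = 0.0;
          for (int e = P.ptr[i]; e < P.ptr[i + 1]; ++e)
            acc += P.w[e] * g_pre_buf[P.pre_local[e]];
          g_sum[P.post[i]] += acc;
          gE_sum[P.post[i]] += acc * P.Esyn;
        }
      }
      ++syn_slot;
    }

    // --- per-cell updates --------------------------------------------------
    for (int i = 0; i < n_cells; ++i) {
      double drive = i_const[i] + ext_gain[i] * v0_now;
      double vi = v[i];
      if (model[i] != 2) {
        double gl = 0.0, bl = 0.0;
        if (model[i] == 1 && pr_row[i] >= 0) {
          gl = Glight[i] * (1.0 - L(pr_row[i], l_seg));
          bl = gl * e_light;
        }
        double g_tot = Gm[i] + g_sum[i] + gl;
        double b = Gm[i] * Erest[i] + gE_sum[i] + bl + drive;
        vi += dt / Cm[i] * (b - g_tot * vi);
        v[i] = vi;
      } else {
        const int r = rgc_slot[i];
        const int cls = rgc_class[i];
        double *gt = &gate[10 * r];
        // first-order gates (Rush-Larsen)
        for (int g = 0; g < 8; ++g) {
          double xi = rate_at(xinf, g, vi), ef = rate_at(efac, g, vi);
          gt[g] = xi + (gt[g] - xi) * ef;
        }
        // coupled T-type inactivation pair
        {
          double ah = rate_at(aT, 0, vi), bh = rate_at(bT, 0, vi);
          double ad = rate_at(aT, 1, vi), bd = rate_at(bT, 1, vi);
          double z = 1.0 - gt[8] - gt[9];
          double hT = gt[8] + dt * (ah * z - bh * gt[8]);
          double dT = gt[9] + dt * (ad * z - bd * gt[9]);
          check_gate(hT); check_gate(dT);
          gt[8] = hT; gt[9] = dT;
        }
        double e_ca = rt_2f * std::log(ca_out / ca_i[r]);
        double m = gt[0], h = gt[1], c = gt[2], nn = gt[3];
        double mA = gt[4], hA = gt[5], nh = gt[6], mT = gt[7];
        double g_na = rgc_g(cls, 0) * m * m * m * h;
        double g_ca = rgc_g(cls, 1) * c * c * c;
        double g_k = rgc_g(cls, 2) * nn * nn * nn * nn;
        double g_ka = rgc_g(cls, 3) * mA * mA * mA * hA;
        double mkca = (ca_i[r] / ca_diss) * (ca_i[r] / ca_diss);
        mkca = mkca / (1.0 + mkca);
        double g_kca = rgc_g(cls, 4) * mkca;
        double g_h = rgc_g(cls, 5) * nh;
        double g_cat = rgc_g(cls, 6) * mT * mT * mT * gt[8];
        // calcium pool (influx from Ca channels only)
        double i_ca_in = (g_ca + g_cat) * (e_ca - vi);
        ca_i[r] += dt * (ca_k_in * std::max(i_ca_in, 0.0) -
                         (ca_i[r] - ca_rest) / ca_tau);
        if (ca_i[r] < 1e-9) ca_i[r] = 1e-9;
        double g_tot = Gm[i] + g_sum[i] + g_na + g_ca + g_k + g_ka +
                       g_kca + g_h + g_cat;
        double b = Gm[i] * Erest[i] + gE_sum[i] + drive +
                   g_na * rgc_e(cls, 0) + (g_ca + g_cat) * e_ca +
                   (g_k + g_ka + g_kca) * rgc_e(cls, 1) +
                   g_h * rgc_e(cls, 2);
        double v_inf = b / g_tot;
        double v_new = v_inf + (vi - v_inf) * std::exp(-dt * g_tot / Cm[i]);
        if (vi < spike_v && v_new >= spike_v && t - last_spike[r] >= lockout) {
          last_spike[r] = t;
          spike_cell.push_back(i + 1);   // back to 1-based ids
          spike_t.push_back(now + dt);
        }
        v[i] = v_new;
      }
      if (!std::isfinite(v[i]))
        stop("integration failure: non-finite voltage in cell %d at t = %.3f ms",
             i + 1, now);
    }

    if (n_trace_t > 0 && t % trace_stride == 0) {
      for (int j = 0; j < trace_cells.size(); ++j)
        traces(j, trace_col) = v[trace_cells[j]];
      trace_times[trace_col] = now + dt;
      ++trace_col;
    }
  }

  return List::create(
      _["spike_cell"] = wrap(spike_cell),
      _["spike_t"] = wrap(spike_t),
      _["traces"] = traces,
      _["trace_t"] = wrap(trace_times),
      _["v_final"] = wrap(v));
}
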