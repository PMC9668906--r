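// Numerical kernels for the 1-D water-column simulator.
//
// Layer convention: index 0 is the surface layer, depth positive downward,
// uniform thickness dz.  Interface i sits between layers i and i+1, so a
// column of n layers has n-1 interior interfaces.  Diffusivities are defined
// on interfaces; state variables on layer mid-points.
//
// Units used throughout:
//   temperature  degC            density   kg/m3
//   PHY/ZOO/POC  mgC/m3          DIN       ugN/L (= mgN/m3)
//   DIP          ugP/L (= mgP/m3)
//   DO           mg/L  (= g/m3)
//   sediment     gC/m2, gN/m2, gP/m2
//   fluxes       W/m2 (heat), conc * m / day (tracers)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SIGMA_SB = 5.670374e-8; // W m-2 K-4
static const double SECS_PER_DAY = 86400.0;

// ---------------------------------------------------------------------------
// Equation of state: freshwater density polynomial in T (salinity 0).
// Maximum at 3.98 degC, rho(4) = 999.972 kg/m3.
static inline double dens1(double t) {
  return 999.842594 + t * (6.793952e-2 + t * (-9.095290e-3 +
         t * (1.001685e-4 + t * (-1.120083e-6 + t * 6.536332e-9))));
}

// [[Rcpp::export]]
NumericVector water_density_cpp(NumericVector temp) {
  int n = temp.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dens1(temp[i]);
  return out;
}

// ---------------------------------------------------------------------------
// DO solubility at 1 atm (Benson-Krause), mg/L; 14.62 mg/L at 0 degC.
static inline double dosat1(double t) {
  double tk = t + 273.15;
  double lnc = -139.34411 + 1.575701e5 / tk - 6.642308e7 / (tk * tk)
             + 1.243800e10 / (tk * tk * tk) - 8.621949e11 / (tk * tk * tk * tk);
  return std::exp(lnc);
}

// [[Rcpp::export]]
NumericVector do_saturation_cpp(NumericVector temp) {
  int n = temp.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dosat1(temp[i]);
  return out;
}

// saturation vapour pressure over water, hPa (Magnus)
static inline double esat_hpa(double t) {
  return 6.112 * std::exp(17.67 * t / (t + 243.5));
}

// ---------------------------------------------------------------------------
// Surface heat budget.  Returns (shortwave_abs, longwave_net, sensible,
// latent, total, sw_penetrating); positive = into the lake.
// shortwave_abs is the full absorbed shortwave (1 - albedo) * sw; the
// fraction (1 - sw_surface_frac) of it penetrates below the surface layer
// and is reported separately as sw_penetrating (part of shortwave_abs).
// [[Rcpp::export]]
NumericVector surface_heat_flux_cpp(double air_temp, double wind_land,
                                    double cloud, double shortwave,
                                    double t_surface, List p) {
  double albedo   = as<double>(p["albedo"]);
  double beta     = as<double>(p["sw_surface_frac"]);
  double eps      = as<double>(p["emissivity"]);
  double rh       = as<double>(p["rel_humidity"]);
  double c_cloud  = as<double>(p["cloud_lw_coef"]);
  double c_sens   = as<double>(p["c_sensible"]);
  double c_lat    = as<double>(p["c_latent"]);
  double rho_air  = as<double>(p["rho_air"]);
  double cp_air   = as<double>(p["cp_air"]);
  double lv       = as<double>(p["latent_heat_vap"]);
  double wfac     = as<double>(p["wind_factor"]);

  double w = wfac * wind_land; // over-lake wind
  double sw_abs = (1.0 - albedo) * shortwave;
  double sw_pen = (1.0 - beta) * sw_abs;

  double ea  = rh * esat_hpa(air_temp); // hPa
  double tsk = t_surface + 273.15;
  // Berliand-type bulk longwave: clear-sky back radiation deficit with
  // cloud correction, plus a surface-air temperature correction term.
  double lw_clear = eps * SIGMA_SB * tsk * tsk * tsk * tsk *
                    (0.39 - 0.05 * std::sqrt(ea));
  double lw = -(lw_clear * (1.0 - c_cloud * cloud * cloud) +
                4.0 * eps * SIGMA_SB * tsk * tsk * tsk * (t_surface - air_temp));

  double sens = -rho_air * cp_air * c_sens * w * (t_surface - air_temp);

  double qs = 0.622 * esat_hpa(t_surface) / 1013.25;
  double qa = 0.622 * ea / 1013.25;
  double lat = -rho_air * lv * c_lat * w * (qs - qa);

  double total = sw_abs + lw + sens + lat;
  NumericVector out = NumericVector::create(
    _["shortwave_abs"] = sw_abs, _["longwave_net"] = lw,
    _["sensible"] = sens, _["latent"] = lat,
    _["total"] = total, _["sw_penetrating"] = sw_pen);
  return out;
}

// ---------------------------------------------------------------------------
// Wind-driven vertical diffusivity on the n-1 interior interfaces.
// Surface value scales with friction velocity, decays over a mixing length,
// and is damped where the density profile is stably stratified
// (Richardson-number-style damping on N^2).
// [[Rcpp::export]]
NumericVector wind_diffusivity_cpp(double wind_land, NumericVector density,
                                   double dz, List p) {
  double wfac  = as<double>(p["wind_factor"]);
  double cdrag = as<double>(p["c_drag"]);
  double rhoa  = as<double>(p["rho_air"]);
  double rho0  = as<double>(p["rho0"]);
  double ck    = as<double>(p["c_k"]);
  double lmix  = as<double>(p["l_mix"]);
  double kbg   = as<double>(p["k_background"]);
  double n0sq  = as<double>(p["n0_sq"]);
  double riexp = as<double>(p["ri_exp"]);
  double g     = 9.81;

  int n = density.size();
  NumericVector K(n - 1);
  double w = wfac * wind_land;
  double ustar = w * std::sqrt(rhoa * cdrag / rho0);
  double k0 = ck * ustar * lmix;
  for (int i = 0; i < n - 1; ++i) {
    double z = (i + 1) * dz;
    double n2 = (g / rho0) * (density[i + 1] - density[i]) / dz;
    if (n2 < 0.0) n2 = 0.0;
    double damp = std::pow(1.0 + n2 / n0sq, riexp);
    K[i] = kbg + k0 * std::exp(-z / lmix) / damp;
  }
  return K;
}

// ---------------------------------------------------------------------------
// Implicit (backward Euler) vertical diffusion, flux form, Thomas solve.
// K on the n-1 interior interfaces; flux_top/flux_bottom are boundary fluxes
// in conc * m / s, positive into the column.  Conserves sum(C*dz) exactly
// (to round-off) when both fluxes are zero.
static void diffuse_inplace(std::vector<double>& c, const double* K,
                            int n, double dt, double dz,
                            double flux_top, double flux_bottom,
                            std::vector<double>& cp, std::vector<double>& dp) {
  // rows: -lam[i-1] c[i-1] + (1 + lam[i-1] + lam[i]) c[i] - lam[i] c[i+1] = rhs
  double fac = dt / (dz * dz);
  cp.resize(n); dp.resize(n);
  std::vector<double> lam(n - 1);
  for (int i = 0; i < n - 1; ++i) lam[i] = K[i] * fac;

  // RHS with boundary fluxes
  std::vector<double> rhs(c);
  rhs[0]     += flux_top * dt / dz;
  rhs[n - 1] += flux_bottom * dt / dz;

  // Thomas algorithm
  double b0 = 1.0 + lam[0];
  cp[0] = -lam[0] / b0;
  dp[0] = rhs[0] / b0;
  for (int i = 1; i < n; ++i) {
    double a = (i > 0) ? -lam[i - 1] : 0.0;
    double b = 1.0 + ((i > 0) ? lam[i - 1] : 0.0) + ((i < n - 1) ? lam[i] : 0.0);
    double cc = (i < n - 1) ? -lam[i] : 0.0;
    double m = b - a * cp[i - 1];
    cp[i] = cc / m;
    dp[i] = (rhs[i] - a * dp[i - 1]) / m;
  }
  c[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) c[i] = dp[i] - cp[i] * c[i + 1];
}

// [[Rcpp::export]]
NumericVector diffuse_cpp(NumericVector conc, NumericVector K, double dt,
                          double dz, double flux_top = 0.0,
                          double flux_bottom = 0.0) {
  int n = conc.size();
  if (K.size() != n - 1) stop("K must have length(conc) - 1 (interfaces)");
  if (dt <= 0) stop("dt must be positive");
  if (n < 2) stop("degenerate grid: need at least 2 layers");
  std::vector<double> c(conc.begin(), conc.end()), cp, dp;
  diffuse_inplace(c, REAL(K), n, dt, dz, flux_top, flux_bottom, cp, dp);
  return NumericVector(c.begin(), c.end());
}

// ---------------------------------------------------------------------------
// Convective adjustment: merge unstable contiguous regions (density
// decreasing with depth) into volume-weighted homogeneous blocks, rechecking
// upward after each merge (mixed-region stack algorithm).  Temperature and
// all passive tracers are homogenized together; heat and tracer mass are
// conserved exactly.  Layers have equal thickness so volume weights are
// layer counts.
static void convect_inplace(std::vector<double>& temp,
                            std::vector<std::vector<double> >& tracers) {
  int n = (int)temp.size();
  int ntr = (int)tracers.size();
  // regions: start index, layer count, mean temp, mean tracer values
  std::vector<int> rstart(n), rcount(n);
  std::vector<double> rtemp(n);
  std::vector<std::vector<double> > rtr(ntr, std::vector<double>(n));
  int m = 0; // number of regions on the stack
  for (int k = 0; k < n; ++k) {
    rstart[m] = k; rcount[m] = 1; rtemp[m] = temp[k];
    for (int t = 0; t < ntr; ++t) rtr[t][m] = tracers[t][k];
    ++m;
    while (m >= 2 && dens1(rtemp[m - 2]) > dens1(rtemp[m - 1]) + 1e-12) {
      // merge the two topmost-of-stack regions (upper is m-2)
      double w1 = rcount[m - 2], w2 = rcount[m - 1], w = w1 + w2;
      rtemp[m - 2] = (w1 * rtemp[m - 2] + w2 * rtemp[m - 1]) / w;
      for (int t = 0; t < ntr; ++t)
        rtr[t][m - 2] = (w1 * rtr[t][m - 2] + w2 * rtr[t][m - 1]) / w;
      rcount[m - 2] = (int)w;
      --m;
    }
  }
  for (int r = 0; r < m; ++r) {
    for (int k = rstart[r]; k < rstart[r] + rcount[r]; ++k) {
      temp[k] = rtemp[r];
      for (int t = 0; t < ntr; ++t) tracers[t][k] = rtr[t][r];
    }
  }
}

// [[Rcpp::export]]
List convective_adjustment_cpp(NumericVector temp, NumericMatrix tracers) {
  int n = temp.size();
  int ntr = tracers.ncol();
  if (ntr > 0 && tracers.nrow() != n)
    stop("tracers must have one row per layer");
  std::vector<double> t(temp.begin(), temp.end());
  std::vector<std::vector<double> > tr(ntr, std::vector<double>(n));
  for (int j = 0; j < ntr; ++j)
    for (int i = 0; i < n; ++i) tr[j][i] = tracers(i, j);
  convect_inplace(t, tr);
  NumericVector tout(t.begin(), t.end());
  NumericMatrix trout(n, ntr);
  for (int j = 0; j < ntr; ++j)
    for (int i = 0; i < n; ++i) trout(i, j) = tr[j][i];
  return List::create(_["temp"] = tout, _["tracers"] = trout);
}

// ---------------------------------------------------------------------------
// First-order upwind sinking (downward); explicit, requires w*dt <= dz.
// Mass leaving the bottom layer is returned as flux_to_sediment
// (conc units * m, i.e. mass per unit area for this dt).
// [[Rcpp::export]]
List sinking_cpp(NumericVector conc, double w_mday, double dt_days, double dz) {
  int n = conc.size();
  double wdt = w_mday * dt_days;
  if (wdt > dz * (1.0 + 1e-12)) stop("sinking CFL violated: w*dt > dz");
  double cr = wdt / dz;
  NumericVector out(n);
  double to_sed = conc[n - 1] * wdt;
  out[0] = conc[0] * (1.0 - cr);
  for (int i = 1; i < n; ++i) out[i] = conc[i] * (1.0 - cr) + conc[i - 1] * cr;
  return List::create(_["conc"] = out, _["flux_to_sediment"] = to_sed);
}

// ---------------------------------------------------------------------------
// Ecosystem parameter bundle
struct EcoP {
  double mu_max, q10, t_ref, k_i, k_n, k_p, r_phy, m_phy, g_max, ivlev,
         assim_eff, r_zoo, m_zoo, k_dec, w_phy, w_poc, k_rea, k_sed, sed_q10,
         p_enh_a, k_do_sed, rnc, rpc, roc, do_cap, kext_w, kext_poc;
  bool excrete_direct;
};
static EcoP read_ecop(List p) {
  EcoP e;
  e.mu_max = as<double>(p["mu_max"]);   e.q10 = as<double>(p["q10"]);
  e.t_ref = as<double>(p["t_ref"]);     e.k_i = as<double>(p["k_light"]);
  e.k_n = as<double>(p["k_din"]);       e.k_p = as<double>(p["k_dip"]);
  e.r_phy = as<double>(p["r_phy"]);     e.m_phy = as<double>(p["m_phy"]);
  e.g_max = as<double>(p["g_max"]);     e.ivlev = as<double>(p["ivlev"]);
  e.assim_eff = as<double>(p["assim_eff"]);
  e.r_zoo = as<double>(p["r_zoo"]);     e.m_zoo = as<double>(p["m_zoo"]);
  e.k_dec = as<double>(p["k_dec"]);     e.w_phy = as<double>(p["w_phy"]);
  e.w_poc = as<double>(p["w_poc"]);     e.k_rea = as<double>(p["k_rea"]);
  e.k_sed = as<double>(p["k_sed"]);     e.sed_q10 = as<double>(p["sed_q10"]);
  e.p_enh_a = as<double>(p["p_enh_a"]); e.k_do_sed = as<double>(p["k_do_sed"]);
  e.rnc = as<double>(p["ratio_nc"]);    e.rpc = as<double>(p["ratio_pc"]);
  e.roc = as<double>(p["ratio_oc"]);    e.do_cap = as<double>(p["do_cap"]);
  e.kext_w = as<double>(p["kext_w"]);   e.kext_poc = as<double>(p["kext_poc"]);
  e.excrete_direct = as<bool>(p["excrete_direct"]);
  return e;
}

static inline double ftemp(double t, double q10, double tref) {
  return std::pow(q10, (t - tref) / 10.0);
}

// Instantaneous (uncapped) biochemical tendencies, per day, for one column.
// state columns: PHY ZOO DIN DIP DO POC.  light is the irradiance at each
// layer mid-depth (W/m2).
// [[Rcpp::export]]
NumericMatrix eco_tendencies_cpp(NumericMatrix state, NumericVector light,
                                 NumericVector temp, List params) {
  EcoP e = read_ecop(params);
  int n = state.nrow();
  NumericMatrix d(n, 6);
  for (int i = 0; i < n; ++i) {
    double phy = state(i, 0), zoo = state(i, 1), din = state(i, 2),
           dip = state(i, 3), dox = state(i, 4), poc = state(i, 5);
    (void)dox;
    double ft = ftemp(temp[i], e.q10, e.t_ref);
    double fi = light[i] / (e.k_i + light[i]);
    double fn = din / (e.k_n + din);
    double fp = dip / (e.k_p + dip);
    double fnut = std::min(fn, fp);
    double growth = e.mu_max * ft * fi * fnut * phy;
    double resp_p = e.r_phy * ft * phy;
    double mort_p = e.m_phy * phy;
    double graz   = e.g_max * ft * (1.0 - std::exp(-e.ivlev * phy)) * zoo;
    double resp_z = e.r_zoo * ft * zoo;
    double mort_z = e.m_zoo * zoo;
    double dec    = e.k_dec * ft * poc;
    double remin  = resp_p + dec + (e.excrete_direct ? resp_z : 0.0);
    d(i, 0) = growth - resp_p - mort_p - graz;
    d(i, 1) = e.assim_eff * graz - resp_z - mort_z;
    d(i, 5) = mort_p + mort_z + (1.0 - e.assim_eff) * graz - dec +
              (e.excrete_direct ? 0.0 : resp_z);
    d(i, 2) = (-growth + remin) * e.rnc;
    d(i, 3) = (-growth + remin) * e.rpc;
    d(i, 4) = (growth - resp_p - dec -
               (e.excrete_direct ? resp_z : 0.0)) * e.roc / 1000.0;
  }
  return d;
}

// ---------------------------------------------------------------------------
// Physics parameter bundle
struct PhysP {
  double albedo, beta, kext_heat, emissivity, rh, c_cloud, c_sens, c_lat,
         rho_air, cp_air, lv, wind_factor, c_drag, rho0, cp_w,
         k_background, c_k, l_mix, n0_sq, ri_exp;
};
static PhysP read_physp(List p) {
  PhysP q;
  q.albedo = as<double>(p["albedo"]);
  q.beta = as<double>(p["sw_surface_frac"]);
  q.kext_heat = as<double>(p["kext_heat"]);
  q.emissivity = as<double>(p["emissivity"]);
  q.rh = as<double>(p["rel_humidity"]);
  q.c_cloud = as<double>(p["cloud_lw_coef"]);
  q.c_sens = as<double>(p["c_sensible"]);
  q.c_lat = as<double>(p["c_latent"]);
  q.rho_air = as<double>(p["rho_air"]);
  q.cp_air = as<double>(p["cp_air"]);
  q.lv = as<double>(p["latent_heat_vap"]);
  q.wind_factor = as<double>(p["wind_factor"]);
  q.c_drag = as<double>(p["c_drag"]);
  q.rho0 = as<double>(p["rho0"]);
  q.cp_w = as<double>(p["cp_water"]);
  q.k_background = as<double>(p["k_background"]);
  q.c_k = as<double>(p["c_k"]);
  q.l_mix = as<double>(p["l_mix"]);
  q.n0_sq = as<double>(p["n0_sq"]);
  q.ri_exp = as<double>(p["ri_exp"]);
  return q;
}

struct FluxOut { double sw_abs, lw, sens, lat, total, sw_pen; };
static FluxOut flux1(double at, double wl, double cc, double sw, double ts,
                     const PhysP& q) {
  FluxOut f;
  double w = q.wind_factor * wl;
  f.sw_abs = (1.0 - q.albedo) * sw;
  f.sw_pen = (1.0 - q.beta) * f.sw_abs;
  double ea = q.rh * esat_hpa(at);
  double tsk = ts + 273.15;
  double lw_clear = q.emissivity * SIGMA_SB * tsk * tsk * tsk * tsk *
                    (0.39 - 0.05 * std::sqrt(ea));
  f.lw = -(lw_clear * (1.0 - q.c_cloud * cc * cc) +
           4.0 * q.emissivity * SIGMA_SB * tsk * tsk * tsk * (ts - at));
  f.sens = -q.rho_air * q.cp_air * q.c_sens * w * (ts - at);
  double qs = 0.622 * esat_hpa(ts) / 1013.25;
  double qa = 0.622 * ea / 1013.25;
  f.lat = -q.rho_air * q.lv * q.c_lat * w * (qs - qa);
  f.total = f.sw_abs + f.lw + f.sens + f.lat;
  return f;
}

static void windk_inplace(double wl, const std::vector<double>& rho, int n,
                          double dz, const PhysP& q, std::vector<double>& K) {
  double w = q.wind_factor * wl;
  double ustar = w * std::sqrt(q.rho_air * q.c_drag / q.rho0);
  double k0 = q.c_k * ustar * q.l_mix;
  K.resize(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double z = (i + 1) * dz;
    double n2 = (9.81 / q.rho0) * (rho[i + 1] - rho[i]) / dz;
    if (n2 < 0.0) n2 = 0.0;
    K[i] = q.k_background +
           k0 * std::exp(-z / q.l_mix) / std::pow(1.0 + n2 / q.n0_sq, q.ri_exp);
  }
}

// ---------------------------------------------------------------------------
// One physics step on the column: surface heat flux, penetrating shortwave
// absorption, implicit heat diffusion with wind-driven K, convective
// adjustment (temperature and tracers together), river volume exchange at
// the surface layer with matching outflow, density update.
// river = (flow m/day, temp degC, din, dip, do, poc concentrations); pass
// flow = 0 for no river.  Returns new temp, tracers, K used, density, and
// the heat-ledger terms (J/m2) for this step.
// [[Rcpp::export]]
List advance_physics_cpp(NumericVector temp, NumericMatrix tracers,
                         double air_temp, double wind_land, double cloud,
                         double shortwave, NumericVector river,
                         double dt, double dz, List params) {
  PhysP q = read_physp(params);
  int n = temp.size();
  int ntr = tracers.ncol();
  std::vector<double> t(temp.begin(), temp.end());
  std::vector<std::vector<double> > tr(ntr, std::vector<double>(n));
  for (int j = 0; j < ntr; ++j)
    for (int i = 0; i < n; ++i) tr[j][i] = tracers(i, j);

  FluxOut f = flux1(air_temp, wind_land, cloud, shortwave, t[0], q);
  double hc = q.rho0 * q.cp_w * dz; // J/m2 per degC per layer

  // non-penetrating part heats layer 0
  t[0] += (f.total - f.sw_pen) * dt / hc;
  // penetrating shortwave absorbed down the column (Beer-Lambert, constant
  // heat extinction); whatever passes the bottom is deposited in the bottom
  // layer so the column absorbs the full penetrating flux.
  if (f.sw_pen > 0.0) {
    double itop = f.sw_pen;
    for (int i = 0; i < n; ++i) {
      double ibot = f.sw_pen * std::exp(-q.kext_heat * (i + 1) * dz);
      double absorbed = itop - ibot;
      if (i == n - 1) absorbed = itop; // deposit remainder at the bottom
      t[i] += absorbed * dt / hc;
      itop = ibot;
    }
  }

  // diffusivity from pre-diffusion density
  std::vector<double> rho(n), K, cp, dpv;
  for (int i = 0; i < n; ++i) rho[i] = dens1(t[i]);
  windk_inplace(wind_land, rho, n, dz, q, K);
  diffuse_inplace(t, K.data(), n, dt, dz, 0.0, 0.0, cp, dpv);

  convect_inplace(t, tr);

  // river volume exchange at the surface layer (inflow + equal outflow)
  double heat_river_in = 0.0, heat_river_out = 0.0;
  double flow = river[0];
  if (flow > 0.0) {
    double vol = flow * dt / SECS_PER_DAY; // m of water this step
    double rtem = river[1];
    heat_river_in = q.rho0 * q.cp_w * vol * rtem;
    heat_river_out = q.rho0 * q.cp_w * vol * t[0];
    t[0] += (vol / dz) * (rtem - t[0]);
    // tracers: order PHY ZOO DIN DIP DO POC (when 6 are passed)
    if (ntr == 6) {
      double rconc[6] = {0.0, 0.0, river[2], river[3], river[4], river[5]};
      for (int j = 0; j < ntr; ++j)
        tr[j][0] += (vol / dz) * (rconc[j] - tr[j][0]);
    }
    convect_inplace(t, tr); // river water may be denser than the surface
  }

  for (int i = 0; i < n; ++i) rho[i] = dens1(t[i]);

  NumericVector tout(t.begin(), t.end());
  NumericMatrix trout(n, ntr);
  for (int j = 0; j < ntr; ++j)
    for (int i = 0; i < n; ++i) trout(i, j) = tr[j][i];
  return List::create(
    _["temp"] = tout, _["tracers"] = trout,
    _["density"] = NumericVector(rho.begin(), rho.end()),
    _["K"] = NumericVector(K.begin(), K.end()),
    _["flux"] = NumericVector::create(
      _["shortwave_abs"] = f.sw_abs, _["longwave_net"] = f.lw,
      _["sensible"] = f.sens, _["latent"] = f.lat, _["total"] = f.total,
      _["sw_penetrating"] = f.sw_pen),
    _["heat_surface_j"] = f.total * dt,
    _["heat_river_in_j"] = heat_river_in,
    _["heat_river_out_j"] = heat_river_out);
}

// ---------------------------------------------------------------------------
// Full simulation loop.
//
// forcing: list of daily vectors air_temp, wind, cloud, shortwave (length nd)
// river:   list of daily vectors flow (m/day), temp, din, dip, do, poc
// init:    temp (n), eco (n x 6: PHY ZOO DIN DIP DO POC), sed (3: C N P)
// Returns daily-mean archives and whole-run budget accumulators.
// [[Rcpp::export]]
List run_core_cpp(List forcing, List river, NumericVector temp0,
                  NumericMatrix eco0, NumericVector sed0,
                  int steps_per_day, double dz, List phys_params,
                  List eco_params) {
  PhysP q = read_physp(phys_params);
  EcoP e = read_ecop(eco_params);
  NumericVector f_at = forcing["air_temp"], f_ws = forcing["wind"],
                f_cc = forcing["cloud"], f_sw = forcing["shortwave"];
  NumericVector r_fl = river["flow"], r_te = river["temp"],
                r_dn = river["din"], r_dp = river["dip"],
                r_do = river["do"], r_pc = river["poc"];
  int nd = f_at.size();
  int n = temp0.size();
  double dt = SECS_PER_DAY / steps_per_day;
  double dtd = dt / SECS_PER_DAY; // step in days
  double hc = q.rho0 * q.cp_w * dz;

  std::vector<double> t(temp0.begin(), temp0.end());
  std::vector<std::vector<double> > s(6, std::vector<double>(n));
  for (int j = 0; j < 6; ++j)
    for (int i = 0; i < n; ++i) s[j][i] = eco0(i, j);
  double sed_c = sed0[0], sed_n = sed0[1], sed_p = sed0[2];

  // archives (daily means)
  NumericMatrix a_t(nd, n), a_phy(nd, n), a_zoo(nd, n), a_din(nd, n),
                a_dip(nd, n), a_do(nd, n), a_poc(nd, n), a_rho(nd, n);
  NumericMatrix a_sed(nd, 3);

  // budget accumulators (per m2)
  double b_heat_surf = 0, b_heat_riv_in = 0, b_heat_riv_out = 0;
  double b_c_fixed = 0, b_c_resp = 0, b_c_sed_decay = 0;
  double b_c_riv_in = 0, b_c_out = 0;
  double b_n_riv_in = 0, b_n_out = 0, b_p_riv_in = 0, b_p_out = 0;
  double b_o2_air = 0, b_o2_vent = 0, b_o2_bio = 0, b_o2_sed = 0,
         b_o2_riv_in = 0, b_o2_out = 0;

  std::vector<double> rho(n), K, cp, dpv, light(n), kext(n);

  for (int day = 0; day < nd; ++day) {
    double at = f_at[day], ws = f_ws[day], cc = f_cc[day], sw = f_sw[day];
    double rfl = r_fl[day], rte = r_te[day];
    double rconc[6] = {0.0, 0.0, r_dn[day], r_dp[day], r_do[day], r_pc[day]};
    for (int step = 0; step < steps_per_day; ++step) {
      // --- physics: surface fluxes + heat transport -----------------------
      FluxOut f = flux1(at, ws, cc, sw, t[0], q);
      b_heat_surf += f.total * dt;
      t[0] += (f.total - f.sw_pen) * dt / hc;
      if (f.sw_pen > 0.0) {
        double itop = f.sw_pen;
        for (int i = 0; i < n; ++i) {
          double ibot = f.sw_pen * std::exp(-q.kext_heat * (i + 1) * dz);
          double absorbed = (i == n - 1) ? itop : (itop - ibot);
          t[i] += absorbed * dt / hc;
          itop = ibot;
        }
      }
      for (int i = 0; i < n; ++i) rho[i] = dens1(t[i]);
      windk_inplace(ws, rho, n, dz, q, K);
      diffuse_inplace(t, K.data(), n, dt, dz, 0.0, 0.0, cp, dpv);
      convect_inplace(t, s);

      // river volume exchange (inflow at surface, equal outflow)
      if (rfl > 0.0) {
        double vol = rfl * dtd; // m of water
        b_heat_riv_in += q.rho0 * q.cp_w * vol * rte;
        b_heat_riv_out += q.rho0 * q.cp_w * vol * t[0];
        b_c_riv_in += vol * rconc[5];
        b_c_out += vol * (s[0][0] + s[1][0] + s[5][0]);
        b_n_riv_in += vol * (rconc[2] + rconc[5] * e.rnc);
        b_n_out += vol * (s[2][0] + (s[0][0] + s[1][0] + s[5][0]) * e.rnc);
        b_p_riv_in += vol * (rconc[3] + rconc[5] * e.rpc);
        b_p_out += vol * (s[3][0] + (s[0][0] + s[1][0] + s[5][0]) * e.rpc);
        b_o2_riv_in += vol * rconc[4];
        b_o2_out += vol * s[4][0];
        t[0] += (vol / dz) * (rte - t[0]);
        for (int j = 0; j < 6; ++j)
          s[j][0] += (vol / dz) * (rconc[j] - s[j][0]);
        convect_inplace(t, s);
      }

      // --- tracer vertical diffusion (same K as heat) ---------------------
      for (int j = 0; j < 6; ++j)
        diffuse_inplace(s[j], K.data(), n, dt, dz, 0.0, 0.0, cp, dpv);

      // --- sinking of PHY and POC -----------------------------------------
      for (int which = 0; which < 2; ++which) {
        int j = (which == 0) ? 0 : 5;
        double w = (which == 0) ? e.w_phy : e.w_poc;
        if (w <= 0.0) continue;
        double crn = w * dtd / dz;
        double to_sed = s[j][n - 1] * w * dtd; // mgC/m2
        for (int i = n - 1; i >= 1; --i)
          s[j][i] = s[j][i] * (1.0 - crn) + s[j][i - 1] * crn;
        s[j][0] *= (1.0 - crn);
        sed_c += to_sed / 1000.0;          // gC/m2
        sed_n += to_sed * e.rnc / 1000.0;  // gN/m2
        sed_p += to_sed * e.rpc / 1000.0;  // gP/m2
      }

      // --- biochemical tendencies with capped sinks -----------------------
      // light profile at layer mid-depths (POC-dependent extinction)
      {
        double atten = 0.0;
        double i0 = f.sw_pen;
        for (int i = 0; i < n; ++i) {
          double kx = e.kext_w + e.kext_poc * s[5][i];
          light[i] = i0 * std::exp(-(atten + kx * dz * 0.5));
          atten += kx * dz;
        }
      }
      for (int i = 0; i < n; ++i) {
        double phy = s[0][i], zoo = s[1][i], din = s[2][i], dip = s[3][i],
               dox = s[4][i], poc = s[5][i];
        double ft = ftemp(t[i], e.q10, e.t_ref);
        double fi = light[i] / (e.k_i + light[i]);
        double fn = din / (e.k_n + din);
        double fp = dip / (e.k_p + dip);
        double growth = e.mu_max * ft * fi * std::min(fn, fp) * phy;
        double resp_p = e.r_phy * ft * phy;
        double mort_p = e.m_phy * phy;
        double graz = e.g_max * ft * (1.0 - std::exp(-e.ivlev * phy)) * zoo;
        double resp_z = e.r_zoo * ft * zoo;
        double mort_z = e.m_zoo * zoo;
        double dec = e.k_dec * ft * poc;
        // capped-sink positivity: scale each pool's sinks so no pool is
        // driven negative within the step; a process drawing from several
        // pools takes the most restrictive factor.
        double o2_sinks = (resp_p + dec + (e.excrete_direct ? resp_z : 0.0)) *
                          e.roc / 1000.0;
        double f_phy = 1.0, f_zoo = 1.0, f_poc = 1.0, f_din = 1.0,
               f_dip = 1.0, f_do = 1.0;
        double d_phy = (resp_p + mort_p + graz) * dtd;
        if (d_phy > phy && d_phy > 0) f_phy = phy / d_phy;
        double d_zoo = (resp_z + mort_z) * dtd;
        if (d_zoo > zoo && d_zoo > 0) f_zoo = zoo / d_zoo;
        double d_poc = dec * dtd;
        if (d_poc > poc && d_poc > 0) f_poc = poc / d_poc;
        double d_din = growth * e.rnc * dtd;
        if (d_din > din && d_din > 0) f_din = din / d_din;
        double d_dip = growth * e.rpc * dtd;
        if (d_dip > dip && d_dip > 0) f_dip = dip / d_dip;
        double d_do = o2_sinks * dtd;
        if (d_do > dox && d_do > 0) f_do = dox / d_do;
        double g_growth = std::min(f_din, f_dip);
        double g_resp_p = std::min(f_phy, f_do);
        double g_mort_p = f_phy, g_graz = f_phy;
        double g_resp_z = e.excrete_direct ? std::min(f_zoo, f_do) : f_zoo;
        double g_mort_z = f_zoo;
        double g_dec = std::min(f_poc, f_do);
        growth *= g_growth; resp_p *= g_resp_p; mort_p *= g_mort_p;
        graz *= g_graz; resp_z *= g_resp_z; mort_z *= g_mort_z; dec *= g_dec;
        double remin = resp_p + dec + (e.excrete_direct ? resp_z : 0.0);
        s[0][i] = phy + (growth - resp_p - mort_p - graz) * dtd;
        s[1][i] = zoo + (e.assim_eff * graz - resp_z - mort_z) * dtd;
        s[5][i] = poc + (mort_p + mort_z + (1.0 - e.assim_eff) * graz - dec +
                         (e.excrete_direct ? 0.0 : resp_z)) * dtd;
        s[2][i] = din + (-growth + remin) * e.rnc * dtd;
        s[3][i] = dip + (-growth + remin) * e.rpc * dtd;
        s[4][i] = dox + (growth - remin) * e.roc / 1000.0 * dtd;
        b_c_fixed += growth * dtd * dz;
        b_c_resp += remin * dtd * dz;
        b_o2_bio += (growth - remin) * e.roc / 1000.0 * dtd * dz;
      }

      // --- reaeration at the surface --------------------------------------
      if (e.k_rea > 0.0) {
        double dosat = dosat1(t[0]);
        double dflux = e.k_rea * (dosat - s[4][0]) / dz * dtd; // mg/L
        s[4][0] += dflux;
        b_o2_air += dflux * dz;
      }

      // --- sediment exchange at the bottom --------------------------------
      {
        double ftb = ftemp(t[n - 1], e.sed_q10, e.t_ref);
        double dob = s[4][n - 1];
        double decay_c = e.k_sed * ftb * sed_c; // gC/m2/day, aerobic
        double o2_need = decay_c * e.roc / dz * dtd; // mg/L drawn from bottom
        double fa = 1.0;
        if (o2_need > dob && o2_need > 0) fa = dob / o2_need;
        decay_c *= fa;
        double rel_n = e.k_sed * ftb * sed_n * fa;
        double enh = 1.0 + e.p_enh_a * e.k_do_sed / (e.k_do_sed + dob);
        double rel_p = e.k_sed * ftb * sed_p * enh;
        double mx = sed_p / dtd; // cannot release more than the pool
        if (rel_p > mx) rel_p = mx;
        sed_c -= decay_c * dtd; sed_n -= rel_n * dtd; sed_p -= rel_p * dtd;
        s[4][n - 1] -= decay_c * e.roc / dz * dtd;
        s[2][n - 1] += rel_n * 1000.0 / dz * dtd;
        s[3][n - 1] += rel_p * 1000.0 / dz * dtd;
        b_c_sed_decay += decay_c * dtd * 1000.0; // mgC/m2
        b_o2_sed += decay_c * e.roc * dtd;       // g/m2
      }

      // --- supersaturation venting ----------------------------------------
      for (int i = 0; i < n; ++i) {
        double cap = e.do_cap * dosat1(t[i]);
        if (s[4][i] > cap) {
          b_o2_vent += (s[4][i] - cap) * dz;
          s[4][i] = cap;
        }
      }

      // --- accumulate daily means -----------------------------------------
      for (int i = 0; i < n; ++i) {
        a_t(day, i) += t[i];
        a_phy(day, i) += s[0][i]; a_zoo(day, i) += s[1][i];
        a_din(day, i) += s[2][i]; a_dip(day, i) += s[3][i];
        a_do(day, i) += s[4][i];  a_poc(day, i) += s[5][i];
        a_rho(day, i) += dens1(t[i]);
      }
      a_sed(day, 0) += sed_c; a_sed(day, 1) += sed_n; a_sed(day, 2) += sed_p;
    }
    double inv = 1.0 / steps_per_day;
    for (int i = 0; i < n; ++i) {
      a_t(day, i) *= inv; a_phy(day, i) *= inv; a_zoo(day, i) *= inv;
      a_din(day, i) *= inv; a_dip(day, i) *= inv; a_do(day, i) *= inv;
      a_poc(day, i) *= inv; a_rho(day, i) *= inv;
    }
    for (int j = 0; j < 3; ++j) a_sed(day, j) *= inv;
    // integrity: abort on the first non-finite value with a diagnostic
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(t[i]) || !std::isfinite(s[4][i]) ||
          !std::isfinite(s[0][i])) {
        stop("numerical instability: non-finite state at day %d, layer %d",
             day + 1, i + 1);
      }
    }
  }

  NumericVector tend(t.begin(), t.end());
  NumericMatrix send(n, 6);
  for (int j = 0; j < 6; ++j)
    for (int i = 0; i < n; ++i) send(i, j) = s[j][i];

  List budget = List::create(
    _["heat_surface_j"] = b_heat_surf,
    _["heat_river_in_j"] = b_heat_riv_in,
    _["heat_river_out_j"] = b_heat_riv_out,
    _["c_fixed_mg"] = b_c_fixed, _["c_respired_mg"] = b_c_resp,
    _["c_sed_decay_mg"] = b_c_sed_decay,
    _["c_river_in_mg"] = b_c_riv_in, _["c_outflow_mg"] = b_c_out,
    _["n_river_in_mg"] = b_n_riv_in, _["n_outflow_mg"] = b_n_out,
    _["p_river_in_mg"] = b_p_riv_in, _["p_outflow_mg"] = b_p_out,
    _["o2_air_g"] = b_o2_air, _["o2_vented_g"] = b_o2_vent,
    _["o2_bio_g"] = b_o2_bio, _["o2_sed_g"] = b_o2_sed,
    _["o2_river_in_g"] = b_o2_riv_in, _["o2_outflow_g"] = b_o2_out);

  return List::create(
    _["temp"] = a_t, _["density"] = a_rho, _["phy"] = a_phy,
    _["zoo"] = a_zoo, _["din"] = a_din, _["dip"] = a_dip, _["do"] = a_do,
    _["poc"] = a_poc, _["sediment"] = a_sed,
    _["final_temp"] = tend, _["final_eco"] = send,
    _["final_sed"] = NumericVector::create(sed_c, sed_n, sed_p),
    _["budget"] = budget);
}
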