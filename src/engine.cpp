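// Daily forward map for the single-box age-structured food web.
//
// Order of operations per day (fixed, mirrored by the pure-R engine):
//   forcing -> grazing (with prey-standing-stock cap) -> prey removal ->
//   growth allocation -> mortality -> annual recruitment (spawn day) ->
//   annual aging (day 365) -> recording.
//
// All loss flows (egestion, growth overflow, maintenance, mortality, unspent
// spawn) are routed to the detritus component, so a web without producer
// forcing conserves total nitrogen exactly.

#include <Rcpp.h>
using namespace Rcpp;

static const double WR_FLOOR = 1e-8;

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List pk) {
  const int ncomp = as<int>(pk["ncomp"]);
  const IntegerVector kind = pk["kind"];          // 0 pool, 1 vert, 2 producer, 3 detritus
  const IntegerVector nage = pk["nage"];
  const int maxage = as<int>(pk["maxage"]);
  const NumericMatrix mum = pk["mum"];            // maxage x ncomp
  const NumericMatrix Cmat = pk["C"];
  const NumericVector E = pk["E"];
  const NumericVector mL = pk["mL"];
  const NumericVector mQj = pk["mQj"];
  const NumericVector mQa = pk["mQa"];
  const NumericVector mSt_thr = pk["mSt_thr"];
  const NumericVector mSt_rate = pk["mSt_rate"];
  const IntegerVector maturity = pk["maturity"];
  const NumericVector spawn_frac = pk["spawn_frac"];
  const NumericVector spawn_thr = pk["spawn_thr"];
  const NumericVector growth_split = pk["growth_split"];
  const NumericVector maint_frac = pk["maint_frac"];
  const NumericVector w0s = pk["w0s"];
  const NumericVector w0r = pk["w0r"];
  const IntegerVector rec_mode = pk["rec_mode"];  // 0 none, 1 BH, 2 constant
  const NumericVector BHa = pk["BHa"];
  const NumericVector BHb = pk["BHb"];
  const NumericVector KDENR = pk["KDENR"];
  const NumericMatrix avail = pk["avail"];        // pred x prey
  const NumericMatrix forcing = pk["forcing"];    // 365 x ncomp (producers)
  const NumericMatrix deviates = pk["deviates"];  // nyears x ncomp
  const int det = as<int>(pk["det_idx"]);         // 0-based, -1 if absent
  const int ndays = as<int>(pk["ndays"]);
  const int spawn_day = as<int>(pk["spawn_day"]);
  const int record_every = as<int>(pk["record_every"]);
  const double dt = as<double>(pk["dt"]);

  NumericVector B = clone(as<NumericVector>(pk["B0"]));
  NumericMatrix Num = clone(as<NumericMatrix>(pk["Num0"]));   // maxage x ncomp
  NumericMatrix Ws = clone(as<NumericMatrix>(pk["Ws0"]));
  NumericMatrix Wr = clone(as<NumericMatrix>(pk["Wr0"]));

  const int nrec = 1 + (record_every > 0 ? ndays / record_every : 0);
  NumericMatrix rec_bio(nrec, ncomp);
  NumericVector rec_totn(nrec);
  IntegerVector rec_day(nrec);
  NumericVector bank(ncomp), pending(ncomp);

  // annual vertebrate state (recorded at each day-365, post-aging)
  List vNum(ncomp), vWs(ncomp), vWr(ncomp);
  int nyr_rec = ndays / 365;
  for (int j = 0; j < ncomp; ++j) {
    if (kind[j] == 1) {
      vNum[j] = NumericMatrix(nyr_rec, nage[j]);
      vWs[j] = NumericMatrix(nyr_rec, nage[j]);
      vWr[j] = NumericMatrix(nyr_rec, nage[j]);
    }
  }

  NumericVector bio(ncomp);
  NumericMatrix ba(maxage, ncomp);      // per-age vertebrate biomass
  NumericVector prey_loss(ncomp), scale(ncomp), assim_pool(ncomp);
  NumericMatrix assim_age(maxage, ncomp);

  // predator units (pool, or vertebrate age class), fixed over the run
  std::vector<int> unit_comp, unit_age;
  for (int j = 0; j < ncomp; ++j) {
    if (kind[j] == 2 || kind[j] == 3) continue;
    const int na = (kind[j] == 1) ? nage[j] : 1;
    for (int a = 0; a < na; ++a) {
      unit_comp.push_back(j);
      unit_age.push_back(a);
    }
  }
  const int nunits = (int)unit_comp.size();
  std::vector<double> flux((size_t)nunits * ncomp, 0.0);

  auto comp_bio = [&](int j) -> double {
    if (kind[j] != 1) return B[j];
    double s = 0.0;
    for (int a = 0; a < nage[j]; ++a) s += Num(a, j) * (Ws(a, j) + Wr(a, j));
    return s;
  };

  auto record = [&](int slot, int day) {
    double tot = 0.0;
    for (int j = 0; j < ncomp; ++j) {
      double b = comp_bio(j);
      rec_bio(slot, j) = b;
      tot += b + bank[j];
    }
    rec_totn[slot] = tot;
    rec_day[slot] = day;
  };
  record(0, 0);
  int slot = 1;

  for (int day = 1; day <= ndays; ++day) {
    const int doy = (day - 1) % 365 + 1;
    const int year = (day - 1) / 365;  // 0-based

    // 1. producer forcing
    for (int j = 0; j < ncomp; ++j)
      if (kind[j] == 2) B[j] = forcing(doy - 1, j);

    // 2. standing biomass
    for (int j = 0; j < ncomp; ++j) {
      bio[j] = comp_bio(j);
      if (kind[j] == 1)
        for (int a = 0; a < nage[j]; ++a)
          ba(a, j) = Num(a, j) * (Ws(a, j) + Wr(a, j));
    }

    // 3. grazing fluxes per predator unit, prey cap, assimilation
    std::fill(prey_loss.begin(), prey_loss.end(), 0.0);
    std::fill(assim_pool.begin(), assim_pool.end(), 0.0);
    std::fill(assim_age.begin(), assim_age.end(), 0.0);
    double to_det = 0.0;

    // first pass: raw fluxes per (predator unit, prey) and per-prey totals
    for (int u = 0; u < nunits; ++u) {
      const int j = unit_comp[u], a = unit_age[u];
      const double Cu = Cmat(a, j);
      const double mu = mum(a, j);
      const double Bu = (kind[j] == 1) ? ba(a, j) : bio[j];
      const size_t base = (size_t)u * ncomp;
      double sb = 0.0;
      for (int k = 0; k < ncomp; ++k)
        if (avail(j, k) > 0.0) sb += avail(j, k) * bio[k];
      if (Cu > 0.0 && Bu > 0.0 && sb > 0.0) {
        const double denom = 1.0 + (Cu / mu) * E[j] * sb;
        const double f = Bu * Cu * dt / denom;
        for (int k = 0; k < ncomp; ++k) {
          if (avail(j, k) > 0.0 && bio[k] > 0.0) {
            const double g = f * avail(j, k) * bio[k];
            flux[base + k] = g;
            prey_loss[k] += g;
          } else flux[base + k] = 0.0;
        }
      } else {
        for (int k = 0; k < ncomp; ++k) flux[base + k] = 0.0;
      }
    }
    for (int k = 0; k < ncomp; ++k)
      scale[k] = (prey_loss[k] > bio[k] && prey_loss[k] > 0.0)
                     ? bio[k] / prey_loss[k] : 1.0;
    for (int u = 0; u < nunits; ++u) {
      const int j = unit_comp[u], a = unit_age[u];
      double intake = 0.0;
      const size_t base = (size_t)u * ncomp;
      for (int k = 0; k < ncomp; ++k) intake += flux[base + k] * scale[k];
      const double as = E[j] * intake;
      if (kind[j] == 1) assim_age(a, j) += as; else assim_pool[j] += as;
      to_det += (1.0 - E[j]) * intake;  // egestion
    }
    for (int k = 0; k < ncomp; ++k)
      if (prey_loss[k] > bio[k]) prey_loss[k] = bio[k];

    // 4. prey removal
    for (int k = 0; k < ncomp; ++k) {
      if (prey_loss[k] <= 0.0) continue;
      if (kind[k] == 1) {
        for (int a = 0; a < nage[k]; ++a) {
          if (ba(a, k) <= 0.0) continue;
          const double la = prey_loss[k] * ba(a, k) / bio[k];
          const double w = Ws(a, k) + Wr(a, k);
          if (w > 0.0) Num(a, k) -= la / w;
          if (Num(a, k) < 0.0) Num(a, k) = 0.0;
        }
      } else {
        B[k] -= prey_loss[k];
        if (B[k] < 0.0) B[k] = 0.0;
      }
    }

    // 5. growth allocation (rates on start-of-day biomass)
    for (int j = 0; j < ncomp; ++j) {
      if (kind[j] == 0) {
        const double cap = mum(0, j) * bio[j] * dt;
        const double gain = std::min(assim_pool[j], cap);
        to_det += assim_pool[j] - gain;
        B[j] += gain;
      } else if (kind[j] == 1) {
        for (int a = 0; a < nage[j]; ++a) {
          const double N = Num(a, j);
          if (N <= 0.0) { to_det += assim_age(a, j); continue; }
          const double gain = std::min(assim_age(a, j) / N, mum(a, j) * dt);
          to_det += assim_age(a, j) - gain * N;
          const double m = maint_frac[j] * mum(a, j) * dt;
          const double avail_res = std::max(Wr(a, j) - WR_FLOOR, 0.0);
          const double pay = std::min(m, gain + avail_res);
          const double net = gain - pay;
          to_det += pay * N;
          if (net >= 0.0) {
            Ws(a, j) += growth_split[j] * net;
            Wr(a, j) += (1.0 - growth_split[j]) * net;
          } else {
            Wr(a, j) += net;
            if (Wr(a, j) < WR_FLOOR) Wr(a, j) = WR_FLOOR;
          }
        }
      }
    }

    // 6. mortality (detritus: remineralization to the unmodelled nutrient
    // pool, i.e. the mass leaves the system; zero by default)
    for (int j = 0; j < ncomp; ++j) {
      if (kind[j] == 3) {
        double rem = (mL[j] + mQa[j] * B[j]) * B[j] * dt;
        if (rem > B[j]) rem = B[j];
        B[j] -= rem;
      } else if (kind[j] == 0) {
        double rem = (mL[j] + mQa[j] * B[j]) * B[j] * dt;
        if (rem > B[j]) rem = B[j];
        B[j] -= rem;
        to_det += rem;
      } else if (kind[j] == 1) {
        for (int a = 0; a < nage[j]; ++a) {
          const double N = Num(a, j);
          if (N <= 0.0) continue;
          const double mq = (a + 1 < maturity[j]) ? mQj[j] : mQa[j];
          double mst = 0.0;
          if (Ws(a, j) > 0.0 && Wr(a, j) / Ws(a, j) < mSt_thr[j])
            mst = mSt_rate[j];
          double rem = (mL[j] + mq * N + mst) * N * dt;
          if (rem > N) rem = N;
          Num(a, j) -= rem;
          to_det += rem * (Ws(a, j) + Wr(a, j));
        }
      }
    }

    // 7. annual recruitment
    if (doy == spawn_day) {
      for (int j = 0; j < ncomp; ++j) {
        if (kind[j] != 1 || rec_mode[j] == 0) continue;
        double Biom = comp_bio(j);
        double Sp = 0.0, nm = 0.0;
        for (int a = maturity[j] - 1; a < nage[j]; ++a) {
          if (Num(a, j) <= 0.0) continue;
          if (Ws(a, j) > 0.0 && Wr(a, j) / Ws(a, j) < spawn_thr[j]) continue;
          const double take = spawn_frac[j] * Wr(a, j);
          Sp += Num(a, j) * take;
          Wr(a, j) -= take;
          nm += Num(a, j);
        }
        double Rc;
        if (rec_mode[j] == 1) {
          Rc = Sp * BHa[j] / (Biom + BHb[j]) * deviates(year, j);
        } else {
          Rc = KDENR[j] * nm;
        }
        const double w0 = w0s[j] + w0r[j];
        const double rc_max = (w0 > 0.0) ? Sp / w0 : 0.0;
        if (Rc > rc_max) Rc = rc_max;
        if (Rc < 0.0) Rc = 0.0;
        bank[j] += Rc * w0;
        to_det += Sp - Rc * w0;
        pending[j] += Rc;
      }
    }

    if (det >= 0) B[det] += to_det;

    // 8. annual aging (plus-group merge, recruits enter class 1)
    if (doy == 365) {
      for (int j = 0; j < ncomp; ++j) {
        if (kind[j] != 1) continue;
        const int n = nage[j];
        NumericVector nn(n), ns(n), nr(n);
        for (int a = 0; a < n; ++a) {
          nn[a] = Num(a, j); ns[a] = Ws(a, j); nr[a] = Wr(a, j);
        }
        if (n > 1) {
          const double tot = nn[n - 1] + nn[n - 2];
          double ws_p = ns[n - 1], wr_p = nr[n - 1];
          if (tot > 0.0) {
            ws_p = (nn[n - 1] * ns[n - 1] + nn[n - 2] * ns[n - 2]) / tot;
            wr_p = (nn[n - 1] * nr[n - 1] + nn[n - 2] * nr[n - 2]) / tot;
          }
          for (int a = n - 2; a >= 1; --a) {
            Num(a, j) = nn[a - 1]; Ws(a, j) = ns[a - 1]; Wr(a, j) = nr[a - 1];
          }
          Num(n - 1, j) = tot; Ws(n - 1, j) = ws_p; Wr(n - 1, j) = wr_p;
        }
        Num(0, j) = pending[j];
        Ws(0, j) = w0s[j];
        Wr(0, j) = w0r[j];
        bank[j] = 0.0;
        pending[j] = 0.0;
        // annual record
        NumericMatrix rn = vNum[j], rs = vWs[j], rr = vWr[j];
        const int yr = day / 365 - 1;
        if (yr >= 0 && yr < rn.nrow()) {
          for (int a = 0; a < n; ++a) {
            rn(yr, a) = Num(a, j); rs(yr, a) = Ws(a, j); rr(yr, a) = Wr(a, j);
          }
        }
      }
    }

    // 9. recording
    if (record_every > 0 && day % record_every == 0) {
      record(slot, day);
      ++slot;
    }

    // sanity: abort on non-finite state (NaN/Inf persist, so a periodic
    // check still localizes the failure)
    if (day % 73 == 0 || day == ndays) {
      for (int j = 0; j < ncomp; ++j) {
        double b = comp_bio(j);
        if (!R_finite(b))
          stop("non-finite biomass for component %d by day %d", j + 1, day);
      }
    }
  }

  return List::create(
      _["biomass"] = rec_bio, _["total_n"] = rec_totn, _["day"] = rec_day,
      _["vert_num"] = vNum, _["vert_ws"] = vWs, _["vert_wr"] = vWr,
      _["final_B"] = B, _["final_Num"] = Num, _["final_Ws"] = Ws,
      _["final_Wr"] = Wr);
}
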