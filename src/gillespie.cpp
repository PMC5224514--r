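#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie) of translation on one
// transcription unit with endonucleolytic cleavage, ribosome rescue and
// reinitiation. Coordinates are 0-based nt offsets in transcript
// orientation; codons are 1-based within each ORF. Event channels:
//   initiation  - per ORF, when the start region is on the initiable
//                 (5'-most) fragment and the first `spacing_nt` nt are clear
//   elongation  - P site advances one codon if the next codon is intact and
//                 the ribosome ahead is >= spacing_nt away
//   termination - stop codon in the A site; ribosome released
//   cleavage    - unoccupied A site fully intact; truncates the mRNA after
//                 the 2nd nt of the A-site codon and stalls the ribosome;
//                 the downstream fragment leaves the initiable pool
//   rescue      - removes a stalled ribosome (cleaved, or run up against a
//                 truncation)
// Ribosomes downstream of a cut stay on their (detached) fragment and keep
// elongating until they terminate or meet their fragment end.

struct Rib {
  int orf;       // 0-based ORF index
  int codon;     // 1-based P-site codon
  bool occ;      // A site stably occupied (immune to cleavage)
  int state;     // 0 active, 1 stalled by its own cleavage
  int frag_end;  // exclusive transcript end of this ribosome's fragment
};

// [[Rcpp::export]]
DataFrame gillespie_tu_cpp(IntegerVector orf_start, IntegerVector orf_ncod,
                           int tu_len, int n_copies, double sim_time,
                           double k_init, double k_elong, double k_cleave,
                           double k_rescue, double p_occ, int spacing_nt) {
  std::vector<int> out_copy, out_orf, out_codon, out_occ, out_state;
  const int n_orf = orf_start.size();
  std::vector<double> rate;
  std::vector<int> etype, eidx;

  for (int cp = 0; cp < n_copies; ++cp) {
    std::vector<Rib> ribs;
    int initiable_end = tu_len;
    double t = 0.0;
    for (;;) {
      rate.clear(); etype.clear(); eidx.clear();
      if (k_init > 0) {
        for (int j = 0; j < n_orf; ++j) {
          if (orf_start[j] + 6 > initiable_end) continue;
          bool blocked = false;
          for (const Rib &r : ribs) {
            int pnt = orf_start[r.orf] + 3 * (r.codon - 1);
            if (pnt >= orf_start[j] && pnt < orf_start[j] + spacing_nt) {
              blocked = true; break;
            }
          }
          if (!blocked) {
            rate.push_back(k_init); etype.push_back(0); eidx.push_back(j);
          }
        }
      }
      for (int i = 0; i < (int)ribs.size(); ++i) {
        const Rib &r = ribs[i];
        int pnt = orf_start[r.orf] + 3 * (r.codon - 1);
        int N = orf_ncod[r.orf];
        if (r.state == 0) {
          bool a_intact = (pnt + 6 <= r.frag_end);
          if (a_intact && k_elong > 0) {
            if (r.codon + 1 == N) {
              rate.push_back(k_elong); etype.push_back(2); eidx.push_back(i);
            } else if (pnt + 9 <= r.frag_end) {
              bool blocked = false;
              for (int m = 0; m < (int)ribs.size(); ++m) {
                if (m == i) continue;
                int p2 = orf_start[ribs[m].orf] + 3 * (ribs[m].codon - 1);
                if (p2 > pnt && p2 - (pnt + 3) < spacing_nt) {
                  blocked = true; break;
                }
              }
              if (!blocked) {
                rate.push_back(k_elong); etype.push_back(1); eidx.push_back(i);
              }
            }
          }
          if (a_intact && k_cleave > 0 && !r.occ) {
            rate.push_back(k_cleave); etype.push_back(3); eidx.push_back(i);
          }
          if (!a_intact && k_rescue > 0) {  // run into a truncation
            rate.push_back(k_rescue); etype.push_back(4); eidx.push_back(i);
          }
        } else if (k_rescue > 0) {
          rate.push_back(k_rescue); etype.push_back(4); eidx.push_back(i);
        }
      }
      double tot = 0.0;
      for (double v : rate) tot += v;
      if (tot <= 0.0) break;
      t += R::exp_rand() / tot;
      if (t > sim_time) break;
      double u = R::unif_rand() * tot;
      int e = 0;
      while (e + 1 < (int)rate.size() && u > rate[e]) { u -= rate[e]; ++e; }
      int w = eidx[e];
      switch (etype[e]) {
      case 0: {
        Rib nr;
        nr.orf = w; nr.codon = 1;
        nr.occ = (R::unif_rand() < p_occ);
        nr.state = 0; nr.frag_end = initiable_end;
        ribs.push_back(nr);
        break;
      }
      case 1: ribs[w].codon += 1; break;
      case 2: ribs.erase(ribs.begin() + w); break;
      case 3: {
        int a = orf_start[ribs[w].orf] + 3 * (ribs[w].codon - 1) + 3;
        int cut = a + 2;  // first 2 nt of the A-site codon remain
        ribs[w].state = 1;
        for (Rib &r2 : ribs) {
          int p2 = orf_start[r2.orf] + 3 * (r2.codon - 1);
          if (p2 < a && r2.frag_end > cut) r2.frag_end = cut;
        }
        if (initiable_end > cut) initiable_end = cut;
        break;
      }
      case 4: ribs.erase(ribs.begin() + w); break;
      }
    }
    for (const Rib &r : ribs) {
      out_copy.push_back(cp + 1);
      out_orf.push_back(r.orf + 1);
      out_codon.push_back(r.codon);
      out_occ.push_back(r.occ ? 1 : 0);
      out_state.push_back(r.state);
    }
  }
  return DataFrame::create(_["copy"] = out_copy, _["orf"] = out_orf,
                           _["codon"] = out_codon, _["occupied"] = out_occ,
                           _["state"] = out_state);
}
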