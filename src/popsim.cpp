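// Forward Wright-Fisher engine over sparse ancestry-block haplotypes.
//
// A haplotype is a partition of the concatenated genome [0, total)
// into half-open ancestry blocks (implicit starts; `ends` strictly
// increasing, last == total) labelled by founder haplotype, plus a
// position-sorted list of new mutations with infinite-sites ids.
// Meiosis splices the two parental haplotypes at Poisson crossovers
// (independent start-haplotype coin per scaffold) and adds
// Poisson(mu * total) fresh mutations.  Uses R's RNG throughout, so
// results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Hap {
  std::vector<int> ends;
  std::vector<int> labels;
  std::vector<int> mpos;
  std::vector<int> mid;
};

struct Seg { int start, end, src; };

static void make_segments(const std::vector<int>& scaf_off,
                          double rec_per_bp,
                          std::vector<Seg>& segs) {
  segs.clear();
  const int nscaf = (int)scaf_off.size() - 1;
  for (int s = 0; s < nscaf; ++s) {
    const int a0 = scaf_off[s], b0 = scaf_off[s + 1];
    const int len = b0 - a0;
    int k = (int)R::rpois((double)len * rec_per_bp);
    std::vector<int> xs(k);
    for (int i = 0; i < k; ++i) xs[i] = a0 + (int)(unif_rand() * len);
    std::sort(xs.begin(), xs.end());
    int src = unif_rand() < 0.5 ? 0 : 1;
    int cur = a0;
    for (int i = 0; i < k; ++i) {
      if (xs[i] > cur) {
        segs.push_back({cur, xs[i], src});
        cur = xs[i];
      }
      src ^= 1;
    }
    segs.push_back({cur, b0, src});
  }
}

static void gamete(const Hap& h0, const Hap& h1,
                   const std::vector<Seg>& segs,
                   double mut_mean, int total, long long& mut_counter,
                   Hap& out) {
  out.ends.clear(); out.labels.clear();
  out.mpos.clear(); out.mid.clear();
  out.ends.reserve(h0.ends.size() + h1.ends.size());
  out.labels.reserve(h0.ends.size() + h1.ends.size());
  size_t bidx[2] = {0, 0};
  size_t midx[2] = {0, 0};
  const Hap* haps[2] = {&h0, &h1};
  for (const Seg& sg : segs) {
    const Hap& h = *haps[sg.src];
    size_t& j = bidx[sg.src];
    while (j < h.ends.size() && h.ends[j] <= sg.start) ++j;
    size_t k = j;
    // copy blocks clipped to [start, end), merging repeated labels
    while (true) {
      int block_end = h.ends[k] < sg.end ? h.ends[k] : sg.end;
      int lab = h.labels[k];
      if (!out.labels.empty() && out.labels.back() == lab) {
        out.ends.back() = block_end;
      } else {
        out.ends.push_back(block_end);
        out.labels.push_back(lab);
      }
      if (h.ends[k] >= sg.end) break;
      ++k;
    }
    j = k;
    // mutations of the active haplotype inside [start, end):
    // a 1-based mutation p occupies [p-1, p), inside iff start < p <= end
    size_t& m = midx[sg.src];
    while (m < h.mpos.size() && h.mpos[m] <= sg.start) ++m;
    while (m < h.mpos.size() && h.mpos[m] <= sg.end) {
      out.mpos.push_back(h.mpos[m]);
      out.mid.push_back(h.mid[m]);
      ++m;
    }
  }
  int nmut = (int)R::rpois(mut_mean);
  if (nmut > 0) {
    std::vector<std::pair<int, int>> nm(nmut);
    for (int i = 0; i < nmut; ++i) {
      nm[i] = {1 + (int)(unif_rand() * total), (int)(++mut_counter)};
    }
    std::sort(nm.begin(), nm.end());
    size_t old_n = out.mpos.size();
    for (auto& pr : nm) { out.mpos.push_back(pr.first);
                          out.mid.push_back(pr.second); }
    // merge the sorted tail into the sorted head, keeping ids aligned
    std::vector<size_t> order(out.mpos.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = i;
    std::inplace_merge(order.begin(), order.begin() + old_n, order.end(),
                       [&](size_t a, size_t b) {
                         return out.mpos[a] < out.mpos[b];
                       });
    std::vector<int> mp(out.mpos.size()), mi(out.mpos.size());
    for (size_t i = 0; i < order.size(); ++i) {
      mp[i] = out.mpos[order[i]];
      mi[i] = out.mid[order[i]];
    }
    out.mpos.swap(mp);
    out.mid.swap(mi);
  }
}

// [[Rcpp::export(name = "popsim_engine")]]
List popsim_engine(IntegerVector scaf_len, IntegerVector pop_sizes,
                   double rec_per_bp, double mu_per_bp,
                   int n_founders, int n_samples) {
  const int nscaf = scaf_len.size();
  std::vector<int> scaf_off(nscaf + 1, 0);
  for (int i = 0; i < nscaf; ++i) scaf_off[i + 1] = scaf_off[i] + scaf_len[i];
  const int total = scaf_off[nscaf];
  const double mut_mean = mu_per_bp * (double)total;

  // generation 0: n_founders individuals, single-block haplotypes
  std::vector<Hap> cur(2 * n_founders);
  for (int i = 0; i < 2 * n_founders; ++i) {
    cur[i].ends.assign(1, total);
    cur[i].labels.assign(1, i + 1);  // founder labels are 1-based
  }
  long long mut_counter = 0;
  std::vector<Seg> segs;
  std::vector<Hap> nxt;
  for (int t = 0; t < pop_sizes.size(); ++t) {
    const int n_cur = (int)cur.size() / 2;
    const int n_new = pop_sizes[t];
    nxt.assign(2 * n_new, Hap());
    for (int i = 0; i < n_new; ++i) {
      int pa = (int)(unif_rand() * n_cur);
      int pb = pa;
      if (n_cur > 1) {
        while (pb == pa) pb = (int)(unif_rand() * n_cur);
      }
      make_segments(scaf_off, rec_per_bp, segs);
      gamete(cur[2 * pa], cur[2 * pa + 1], segs, mut_mean, total,
             mut_counter, nxt[2 * i]);
      make_segments(scaf_off, rec_per_bp, segs);
      gamete(cur[2 * pb], cur[2 * pb + 1], segs, mut_mean, total,
             mut_counter, nxt[2 * i + 1]);
    }
    cur.swap(nxt);
    Rcpp::checkUserInterrupt();
  }

  // sample n_samples distinct individuals from the final generation
  const int n_final = (int)cur.size() / 2;
  const int n_out = n_samples < n_final ? n_samples : n_final;
  std::vector<int> ids(n_final);
  for (int i = 0; i < n_final; ++i) ids[i] = i;
  for (int i = 0; i < n_out; ++i) {
    int j = i + (int)(unif_rand() * (n_final - i));
    std::swap(ids[i], ids[j]);
  }
  List out(n_out);
  for (int i = 0; i < n_out; ++i) {
    const Hap& a = cur[2 * ids[i]];
    const Hap& b = cur[2 * ids[i] + 1];
    out[i] = List::create(
      Named("ends1") = NumericVector(a.ends.begin(), a.ends.end()),
      Named("labels1") = IntegerVector(a.labels.begin(), a.labels.end()),
      Named("mut_pos1") = NumericVector(a.mpos.begin(), a.mpos.end()),
      Named("mut_id1") = NumericVector(a.mid.begin(), a.mid.end()),
      Named("ends2") = NumericVector(b.ends.begin(), b.ends.end()),
      Named("labels2") = IntegerVector(b.labels.begin(), b.labels.end()),
      Named("mut_pos2") = NumericVector(b.mpos.begin(), b.mpos.end()),
      Named("mut_id2") = NumericVector(b.mid.begin(), b.mid.end()));
  }
  return out;
}
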