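#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Standard persistence computation by column reduction of the Z/2 boundary
// matrix of a filtered simplicial complex.  Rows of `vertices` must already
// be ordered by (filtration, dimension, lexicographic vertex order); the
// column for a simplex stores the indices of its facets and is reduced until
// its pivot (largest facet index) is unclaimed.

static inline unsigned long long skey(const std::vector<int>& v) {
  unsigned long long k = 0;
  for (size_t i = 0; i < v.size(); ++i)
    k = (k << 16) | (unsigned long long)(v[i] + 1);
  return k;
}

// [[Rcpp::export]]
NumericMatrix reduce_persistence_cpp(IntegerMatrix vertices, IntegerVector dim,
                                     NumericVector filtration, int maxdim_report) {
  int ns = vertices.nrow();
  std::unordered_map<unsigned long long, int> index_of;
  index_of.reserve(ns * 2);
  std::vector<std::vector<int> > simp(ns);
  for (int s = 0; s < ns; ++s) {
    std::vector<int> v;
    for (int c = 0; c < vertices.ncol(); ++c)
      if (vertices(s, c) != NA_INTEGER) v.push_back(vertices(s, c) - 1);
    std::sort(v.begin(), v.end());
    simp[s] = v;
    index_of[skey(v)] = s;
  }

  std::vector<int> pivot_owner(ns, -1);
  std::vector<std::vector<int> > reduced(ns);
  std::vector<char> positive(ns, 1);          // unpaired creators
  std::vector<double> births(ns), deaths(ns);
  std::vector<int> bdim(ns);
  int nbars = 0;

  std::vector<int> col, tmp;
  for (int j = 0; j < ns; ++j) {
    col.clear();
    if (dim[j] > 0) {
      const std::vector<int>& v = simp[j];
      std::vector<int> face(v.size() - 1);
      for (size_t drop = 0; drop < v.size(); ++drop) {
        size_t t = 0;
        for (size_t i = 0; i < v.size(); ++i)
          if (i != drop) face[t++] = v[i];
        auto it = index_of.find(skey(face));
        if (it == index_of.end()) stop("filtration not face-closed");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
    }
    // reduce
    while (!col.empty()) {
      int low = col.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      // symmetric difference with owner's reduced column
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    reduced[owner].begin(), reduced[owner].end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int low = col.back();
      pivot_owner[low] = j;
      reduced[j] = col;
      positive[j] = 0;       // j is a destroyer
      positive[low] = 0;     // low is paired
      bdim[nbars] = dim[low];
      births[nbars] = filtration[low];
      deaths[nbars] = filtration[j];
      ++nbars;
    }
  }
  // unpaired creators -> infinite bars
  std::vector<int> inf_idx;
  for (int s = 0; s < ns; ++s)
    if (positive[s] && dim[s] <= maxdim_report) inf_idx.push_back(s);

  int keep = 0;
  for (int b = 0; b < nbars; ++b) if (bdim[b] <= maxdim_report) ++keep;
  NumericMatrix out(keep + (int)inf_idx.size(), 3);
  int r = 0;
  for (int b = 0; b < nbars; ++b) {
    if (bdim[b] > maxdim_report) continue;
    out(r, 0) = bdim[b]; out(r, 1) = births[b]; out(r, 2) = deaths[b]; ++r;
  }
  for (size_t i = 0; i < inf_idx.size(); ++i) {
    int s = inf_idx[i];
    out(r, 0) = dim[s]; out(r, 1) = filtration[s]; out(r, 2) = R_PosInf; ++r;
  }
  colnames(out) = CharacterVector::create("dimension", "birth", "death");
  return out;
}
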