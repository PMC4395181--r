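#include <Rcpp.h>
using namespace Rcpp;

// Embedded absences on an ordinated matrix: zeros lying strictly inside the
// occupied range of each species (column) plus each site (row). All-zero
// margins have no range and contribute nothing.
// [[Rcpp::export]]
double cpp_count_abs(const IntegerMatrix& m, bool species_only) {
  const int nr = m.nrow(), nc = m.ncol();
  double gaps = 0.0;
  for (int j = 0; j < nc; ++j) {
    int first = -1, last = -1, ones = 0;
    for (int i = 0; i < nr; ++i) {
      if (m(i, j) != 0) {
        if (first < 0) first = i;
        last = i;
        ++ones;
      }
    }
    if (ones > 0) gaps += (last - first + 1) - ones;
  }
  if (!species_only) {
    for (int i = 0; i < nr; ++i) {
      int first = -1, last = -1, ones = 0;
      for (int j = 0; j < nc; ++j) {
        if (m(i, j) != 0) {
          if (first < 0) first = j;
          last = j;
          ++ones;
        }
      }
      if (ones > 0) gaps += (last - first + 1) - ones;
    }
  }
  return gaps;
}

// Fill column (species range) gaps so each species occupies a contiguous run
// of sites.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_ranges(const IntegerMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out = clone(m);
  for (int j = 0; j < nc; ++j) {
    int first = -1, last = -1;
    for (int i = 0; i < nr; ++i) {
      if (m(i, j) != 0) {
        if (first < 0) first = i;
        last = i;
      }
    }
    for (int i = first; i >= 0 && i <= last; ++i) out(i, j) = 1;
  }
  return out;
}

// Species replacements: over all unordered site pairs, the number of species
// pairs (A, B) with A present at one site only and B at the other only.
// For sites i and k this is b_ik * b_ki with b the one-sided differences,
// computed from shared richness.
// [[Rcpp::export]]
double cpp_count_rep(const IntegerMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<double> rs(nr, 0.0);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) rs[i] += m(i, j);
  double rep = 0.0;
  for (int i = 0; i < nr; ++i) {
    for (int k = i + 1; k < nr; ++k) {
      double shared = 0.0;
      for (int j = 0; j < nc; ++j)
        if (m(i, j) != 0 && m(k, j) != 0) shared += 1.0;
      rep += (rs[i] - shared) * (rs[k] - shared);
    }
  }
  return rep;
}

// 2x2 checkerboard swap chain. Each step picks a random pair of rows and a
// random pair of columns; when the 2x2 submatrix is a checkerboard it is
// swapped to its mirror, otherwise the step is a self-loop. Steps count
// ATTEMPTS, not accepted swaps: conditioning on accepted swaps would make
// the walk periodic on bipartite swap graphs (a 2x2 checkerboard would
// alternate deterministically). With self-loops the kernel is symmetric,
// aperiodic and irreducible on the margin class, so its stationary
// distribution is uniform. Uses R's RNG (reproducible under set.seed()).
// [[Rcpp::export]]
IntegerMatrix cpp_swap_chain(const IntegerMatrix& m, double n_steps) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out = clone(m);
  if (nr < 2 || nc < 2) return out;
  for (double step = 0.0; step < n_steps; step += 1.0) {
    int i = (int)(unif_rand() * nr), k = (int)(unif_rand() * nr);
    int j = (int)(unif_rand() * nc), l = (int)(unif_rand() * nc);
    if (i == k || j == l) continue;
    int a = out(i, j), b = out(i, l), c = out(k, j), d = out(k, l);
    if (a == d && b == c && a != b) {
      out(i, j) = b; out(i, l) = a; out(k, j) = d; out(k, l) = c;
    }
  }
  return out;
}
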