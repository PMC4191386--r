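// Toy nearest-neighbour-free folding backend: every Watson-Crick or GU pair
// contributes -1 kcal/mol, hairpin loops enclose at least MIN_LOOP unpaired
// nucleotides. Inside/outside dynamic programming gives the exact partition
// function and base-pair probabilities; stochastic traceback draws from the
// Boltzmann ensemble using R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int MIN_LOOP = 3;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// inside partition function, 1-based into 0-based storage
// Q(i,j) over subsequence i..j; Q = 1 for empty/short regions.
static void inside(const std::string& s, double w,
                   std::vector<std::vector<double> >& Q) {
  int n = (int)s.size();
  Q.assign(n + 2, std::vector<double>(n + 2, 1.0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double q = Q[i][j - 1]; // j unpaired
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        if (can_pair(s[k - 1], s[j - 1])) {
          double left = (k > i) ? Q[i][k - 1] : 1.0;
          q += left * w * Q[k + 1][j - 1];
        }
      }
      Q[i][j] = q;
    }
  }
}

// maximum number of pairs (energy = -pairs)
static void mfe_table(const std::string& s,
                      std::vector<std::vector<int> >& M) {
  int n = (int)s.size();
  M.assign(n + 2, std::vector<int>(n + 2, 0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        if (can_pair(s[k - 1], s[j - 1])) {
          int left = (k > i) ? M[i][k - 1] : 0;
          int v = left + 1 + M[k + 1][j - 1];
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }
}

// canonical traceback: prefer "j unpaired" when optimal, else smallest k
static void mfe_traceback(const std::string& s,
                          const std::vector<std::vector<int> >& M,
                          int i, int j, std::string& db) {
  while (j - i >= MIN_LOOP + 1) {
    if (M[i][j] == M[i][j - 1]) { --j; continue; }
    for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
      if (can_pair(s[k - 1], s[j - 1])) {
        int left = (k > i) ? M[i][k - 1] : 0;
        if (left + 1 + M[k + 1][j - 1] == M[i][j]) {
          db[k - 1] = '(';
          db[j - 1] = ')';
          if (k > i) mfe_traceback(s, M, i, k - 1, db);
          i = k + 1;
          --j;
          break;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List toy_fold_cpp(std::string seq) {
  int n = (int)seq.size();
  std::vector<std::vector<int> > M;
  mfe_table(seq, M);
  std::string db(n, '.');
  if (n > MIN_LOOP + 1) mfe_traceback(seq, M, 1, n, db);
  return List::create(_["structure"] = db,
                      _["energy"] = -(double)M[1][n]);
}

// [[Rcpp::export]]
CharacterVector toy_fold_batch_cpp(CharacterVector seqs) {
  int m = seqs.size();
  CharacterVector out(m);
  for (int t = 0; t < m; ++t) {
    std::string s = as<std::string>(seqs[t]);
    int n = (int)s.size();
    std::vector<std::vector<int> > M;
    mfe_table(s, M);
    std::string db(n, '.');
    if (n > MIN_LOOP + 1) mfe_traceback(s, M, 1, n, db);
    out[t] = db;
  }
  return out;
}

// [[Rcpp::export]]
List toy_partition_cpp(std::string seq, double RT) {
  int n = (int)seq.size();
  double w = std::exp(1.0 / RT);
  std::vector<std::vector<double> > Q;
  inside(seq, w, Q);
  double Z = Q[1][n];

  // outside values O(i,j) for candidate pairs; spans processed largest first
  NumericMatrix P(n, n);
  std::vector<std::vector<double> > O(n + 2, std::vector<double>(n + 2, 0.0));
  for (int len = n; len >= MIN_LOOP + 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (!can_pair(seq[i - 1], seq[j - 1])) continue;
      double o = ((i > 1) ? Q[1][i - 1] : 1.0) * ((j < n) ? Q[j + 1][n] : 1.0);
      for (int k = 1; k < i; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (can_pair(seq[k - 1], seq[l - 1]) && O[k][l] > 0.0) {
            o += w * Q[k + 1][i - 1] * Q[j + 1][l - 1] * O[k][l];
          }
        }
      }
      O[i][j] = o;
      P(i - 1, j - 1) = w * Q[i + 1][j - 1] * o / Z;
    }
  }
  // diagonal: probability of being unpaired
  for (int i = 1; i <= n; ++i) {
    double paired = 0.0;
    for (int j = 1; j <= n; ++j) {
      if (j < i) paired += P(j - 1, i - 1);
      if (j > i) paired += P(i - 1, j - 1);
    }
    P(i - 1, i - 1) = 1.0 - paired;
  }
  return List::create(_["Z"] = Z,
                      _["ensemble_energy"] = -RT * std::log(Z),
                      _["bppm"] = P);
}

static void sample_region(const std::string& s, double w,
                          const std::vector<std::vector<double> >& Q,
                          int i, int j, std::string& db) {
  while (j - i >= MIN_LOOP + 1) {
    double r = unif_rand() * Q[i][j];
    if (r < Q[i][j - 1]) { --j; continue; }
    r -= Q[i][j - 1];
    int chosen = -1;
    for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
      if (can_pair(s[k - 1], s[j - 1])) {
        chosen = k; // last pairable k absorbs any rounding residue
        double left = (k > i) ? Q[i][k - 1] : 1.0;
        double wgt = left * w * Q[k + 1][j - 1];
        if (r < wgt) break;
        r -= wgt;
      }
    }
    if (chosen < 0) { --j; continue; } // j cannot pair: numerically unreachable
    db[chosen - 1] = '(';
    db[j - 1] = ')';
    if (chosen > i) sample_region(s, w, Q, i, chosen - 1, db);
    i = chosen + 1;
    --j;
  }
}

// [[Rcpp::export]]
CharacterVector toy_sample_cpp(std::string seq, int count, double RT) {
  int n = (int)seq.size();
  double w = std::exp(1.0 / RT);
  std::vector<std::vector<double> > Q;
  inside(seq, w, Q);
  CharacterVector out(count);
  GetRNGstate();
  for (int t = 0; t < count; ++t) {
    std::string db(n, '.');
    if (n > MIN_LOOP + 1) sample_region(seq, w, Q, 1, n, db);
    out[t] = db;
  }
  PutRNGstate();
  return out;
}
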