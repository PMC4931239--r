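#include <Rcpp.h>
using namespace Rcpp;

// Birth-death engines for the social-inheritance model family.
// All randomness goes through R's RNG so set.seed() in R gives full
// reproducibility across the R and compiled layers.

static int draw_uniform_other(int n, int excl) {
  // uniform over 0..n-1 excluding excl
  int k = (int)(unif_rand() * (n - 1));
  if (k >= n - 1) k = n - 2;
  return (k >= excl) ? k + 1 : k;
}

static int draw_from_set(const std::vector<int> &set) {
  int k = (int)(unif_rand() * set.size());
  if (k >= (int)set.size()) k = set.size() - 1;
  return set[k];
}

// mode: 0 asexual; 1 two-sex copy-mother-only; 2 two parents drawn at random;
// 3 two parents drawn among connected female-male pairs.
// sex codes: 0 unset, 1 female, 2 male.
// [[Rcpp::export]]
List cpp_sim_core(IntegerMatrix adj_, int steps, double pb, double pn, double pr,
                  IntegerVector sex_, IntegerVector ids_, IntegerVector birth_step_,
                  IntegerVector mother_id_, int next_id, int step_offset, int mode) {
  IntegerMatrix adj = clone(adj_);
  IntegerVector sex = clone(sex_);
  IntegerVector ids = clone(ids_);
  IntegerVector birth_step = clone(birth_step_);
  IntegerVector mother_id = clone(mother_id_);
  const int N = adj.nrow();
  IntegerMatrix lineage(steps, 6); // step, newborn, mother, father, dead, degree

  std::vector<int> cand;
  cand.reserve(N);

  for (int t = 0; t < steps; ++t) {
    int step_no = step_offset + t + 1;
    int dead = (int)(unif_rand() * N);
    if (dead >= N) dead = N - 1;
    int dead_id = ids[dead];
    for (int j = 0; j < N; ++j) { adj(dead, j) = 0; adj(j, dead) = 0; }

    int mother = -1, father = -1;
    if (mode == 0) {
      mother = draw_uniform_other(N, dead);
    } else {
      cand.clear();
      for (int j = 0; j < N; ++j)
        if (j != dead && sex[j] == 1) cand.push_back(j);
      if (cand.empty())
        stop("no living female available as mother at step %d", step_no);
      if (mode == 3) {
        // connected female-male pairs among survivors
        std::vector<int> fs, ms;
        for (size_t a = 0; a < cand.size(); ++a) {
          int f = cand[a];
          for (int m = 0; m < N; ++m)
            if (m != dead && sex[m] == 2 && adj(f, m) == 1) {
              fs.push_back(f); ms.push_back(m);
            }
        }
        if (fs.empty())
          stop("no connected female-male pair available as parents at step %d", step_no);
        int k = (int)(unif_rand() * fs.size());
        if (k >= (int)fs.size()) k = fs.size() - 1;
        mother = fs[k]; father = ms[k];
      } else {
        mother = draw_from_set(cand);
        if (mode == 2) {
          cand.clear();
          for (int j = 0; j < N; ++j)
            if (j != dead && sex[j] == 2) cand.push_back(j);
          if (cand.empty())
            stop("no living male available as father at step %d", step_no);
          father = draw_from_set(cand);
        }
      }
    }

    // newborn occupies the dead slot; bond to each survivor
    int deg = 0;
    for (int j = 0; j < N; ++j) {
      if (j == dead) continue;
      double p;
      if (j == mother || j == father) p = pb;
      else if (adj(mother, j) == 1 || (father >= 0 && adj(father, j) == 1)) p = pn;
      else p = pr;
      int e = (unif_rand() < p) ? 1 : 0;
      adj(dead, j) = e; adj(j, dead) = e;
      deg += e;
    }

    lineage(t, 0) = step_no;
    lineage(t, 1) = next_id;
    lineage(t, 2) = ids[mother];
    lineage(t, 3) = (father >= 0) ? ids[father] : NA_INTEGER;
    lineage(t, 4) = dead_id;
    lineage(t, 5) = deg;

    ids[dead] = next_id++;
    birth_step[dead] = step_no;
    mother_id[dead] = ids[mother];
    if (mode > 0) sex[dead] = (unif_rand() < 0.5) ? 1 : 2;
  }

  return List::create(_["adj"] = adj, _["ids"] = ids, _["sex"] = sex,
                      _["birth_step"] = birth_step, _["mother_id"] = mother_id,
                      _["next_id"] = next_id, _["lineage"] = lineage);
}

static double reflect01(double x) {
  x -= 2.0 * std::floor(x / 2.0); // x mod 2, in [0, 2)
  if (x > 1) x = 2.0 - x;
  return x;
}

static double wrap01(double x) {
  x -= std::floor(x);
  return x;
}

// Preference-kernel engines. circular = false: one trait on [0,1], newborn
// bonds its mother with probability pb and every other survivor with
// probability min(1, kscale * exp(-|trait_i - trait_nb| / sscale)); trait
// inherited as in the basic trait model (large mutation mu, Gaussian sigma,
// reflected). circular = true: two traits (display, preference) on the circle
// [0,1); connection probability kscale * exp(-d_ij / sscale) with d_ij the
// circular distance between the newborn's preference and i's display trait;
// no special mother rule; traits inherited with wrapped Gaussian deviations.
// [[Rcpp::export]]
List cpp_sim_kernel(IntegerMatrix adj_, int steps, double pb,
                    NumericMatrix traits_, double mu, double sigma,
                    double kscale, double sscale, bool circular,
                    IntegerVector ids_, IntegerVector birth_step_,
                    IntegerVector mother_id_, int next_id, int step_offset) {
  IntegerMatrix adj = clone(adj_);
  NumericMatrix traits = clone(traits_);
  IntegerVector ids = clone(ids_);
  IntegerVector birth_step = clone(birth_step_);
  IntegerVector mother_id = clone(mother_id_);
  const int N = adj.nrow();
  IntegerMatrix lineage(steps, 6);

  for (int t = 0; t < steps; ++t) {
    int step_no = step_offset + t + 1;
    int dead = (int)(unif_rand() * N);
    if (dead >= N) dead = N - 1;
    int dead_id = ids[dead];
    for (int j = 0; j < N; ++j) { adj(dead, j) = 0; adj(j, dead) = 0; }
    int mother = draw_uniform_other(N, dead);

    // inherit traits
    if (circular) {
      traits(dead, 0) = wrap01(traits(mother, 0) + norm_rand() * sigma);
      traits(dead, 1) = wrap01(traits(mother, 1) + norm_rand() * sigma);
    } else {
      if (unif_rand() < mu) traits(dead, 0) = unif_rand();
      else traits(dead, 0) = reflect01(traits(mother, 0) + norm_rand() * sigma);
    }

    int deg = 0;
    for (int j = 0; j < N; ++j) {
      if (j == dead) continue;
      double p;
      if (circular) {
        double d = std::fabs(traits(dead, 1) - traits(j, 0));
        if (d > 0.5) d = 1.0 - d;
        p = kscale * std::exp(-d / sscale);
      } else if (j == mother) {
        p = pb;
      } else {
        double x = std::fabs(traits(dead, 0) - traits(j, 0));
        p = kscale * std::exp(-x / sscale);
      }
      if (p > 1) p = 1;
      int e = (unif_rand() < p) ? 1 : 0;
      adj(dead, j) = e; adj(j, dead) = e;
      deg += e;
    }

    lineage(t, 0) = step_no;
    lineage(t, 1) = next_id;
    lineage(t, 2) = ids[mother];
    lineage(t, 3) = NA_INTEGER;
    lineage(t, 4) = dead_id;
    lineage(t, 5) = deg;

    ids[dead] = next_id++;
    birth_step[dead] = step_no;
    mother_id[dead] = ids[mother];
  }

  return List::create(_["adj"] = adj, _["traits"] = traits, _["ids"] = ids,
                      _["birth_step"] = birth_step, _["mother_id"] = mother_id,
                      _["next_id"] = next_id, _["lineage"] = lineage);
}
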