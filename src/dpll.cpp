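// Minimal DPLL SAT solver with two-watched-literal propagation and
// chronological backtracking.  Deliberately simple: the CNF instances
// produced by the bounded workflow encoder are small (hundreds of
// variables), and deterministic branching order matters more than raw
// speed.  Branching always picks the lowest-indexed unassigned variable
// and tries TRUE first, so model enumeration visits tool-sequence
// projections in lexicographic order when the caller registers the
// step/mode variables first.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

namespace {

struct Decision {
  int var;
  bool flipped;
};

class Dpll {
public:
  int nvars;
  std::vector<std::vector<int> > cls;   // clauses; first two slots = watched
  std::vector<std::vector<int> > watch; // lit index -> clause ids watching it
  std::vector<signed char> val;         // 1-based; 0 unassigned, +1, -1
  std::vector<int> trail;
  std::vector<size_t> trail_lim;
  std::vector<Decision> decisions;
  size_t qhead;
  bool root_conflict;

  explicit Dpll(int n) : nvars(n), qhead(0), root_conflict(false) {
    val.assign(n + 1, 0);
    watch.assign(2 * (n + 1), std::vector<int>());
  }

  static int lit_index(int lit) {
    return 2 * std::abs(lit) + (lit < 0 ? 1 : 0);
  }

  signed char value(int lit) const {
    signed char v = val[std::abs(lit)];
    return lit > 0 ? v : static_cast<signed char>(-v);
  }

  void add_clause(const std::vector<int>& lits) { cls.push_back(lits); }

  // (Re)initialise watches and root-level units; call before each solve.
  void init_watches() {
    for (size_t i = 0; i < watch.size(); ++i) watch[i].clear();
    for (size_t ci = 0; ci < cls.size(); ++ci) {
      std::vector<int>& c = cls[ci];
      if (c.size() >= 2) {
        watch[lit_index(c[0])].push_back(static_cast<int>(ci));
        watch[lit_index(c[1])].push_back(static_cast<int>(ci));
      }
    }
  }

  void assign(int lit) {
    val[std::abs(lit)] = lit > 0 ? 1 : -1;
    trail.push_back(lit);
  }

  // Propagate everything on the trail; false on conflict.
  bool propagate() {
    while (qhead < trail.size()) {
      int p = trail[qhead++];
      int fidx = lit_index(-p); // clauses watching -p must be visited
      std::vector<int>& wl = watch[fidx];
      size_t i = 0, j = 0;
      bool conflict = false;
      for (; i < wl.size(); ++i) {
        int ci = wl[i];
        std::vector<int>& c = cls[ci];
        // ensure the false literal sits in slot 1
        if (c[0] == -p) std::swap(c[0], c[1]);
        if (value(c[0]) == 1) { wl[j++] = ci; continue; } // satisfied
        bool moved = false;
        for (size_t k = 2; k < c.size(); ++k) {
          if (value(c[k]) != -1) { // new watch
            std::swap(c[1], c[k]);
            watch[lit_index(c[1])].push_back(ci);
            moved = true;
            break;
          }
        }
        if (moved) continue; // dropped from this watch list
        wl[j++] = ci;
        if (value(c[0]) == -1) { // conflict
          conflict = true;
          ++i;
          break;
        }
        assign(c[0]); // unit
      }
      if (conflict) {
        for (; i < wl.size(); ++i) wl[j++] = wl[i];
        wl.resize(j);
        return false;
      }
      wl.resize(j);
    }
    return true;
  }

  void undo_to(size_t mark) {
    while (trail.size() > mark) {
      val[std::abs(trail.back())] = 0;
      trail.pop_back();
    }
    qhead = trail.size();
  }

  // Reset assignment state and install root-level facts (unit clauses).
  bool start() {
    undo_to(0);
    trail_lim.clear();
    decisions.clear();
    init_watches();
    for (size_t ci = 0; ci < cls.size(); ++ci) {
      const std::vector<int>& c = cls[ci];
      if (c.empty()) return false;
      if (c.size() == 1) {
        signed char v = value(c[0]);
        if (v == -1) return false;
        if (v == 0) assign(c[0]);
      }
    }
    return propagate();
  }

  int next_unassigned() const {
    for (int v = 1; v <= nvars; ++v)
      if (val[v] == 0) return v;
    return 0;
  }

  // One complete search from scratch; true iff a model was found.
  bool solve() {
    if (!start()) return false;
    while (true) {
      int v = next_unassigned();
      if (v == 0) return true;
      trail_lim.push_back(trail.size());
      Decision d; d.var = v; d.flipped = false;
      decisions.push_back(d);
      assign(v);
      while (!propagate()) {
        while (!decisions.empty() && decisions.back().flipped) {
          undo_to(trail_lim.back());
          trail_lim.pop_back();
          decisions.pop_back();
        }
        if (decisions.empty()) return false;
        undo_to(trail_lim.back());
        decisions.back().flipped = true;
        assign(-decisions.back().var);
      }
    }
  }
};

} // namespace

// Enumerate up to `limit` models of the CNF.  After each model a blocking
// clause over the positively-assigned `project` variables is added, so
// models are distinct in their projection.  Returns a list of 0/1 integer
// vectors (index = variable).
// [[Rcpp::export(name = ".sat_enumerate")]]
List sat_enumerate_cpp(int nvars, List clauses, IntegerVector project,
                       int limit) {
  if (nvars < 0) stop("nvars must be >= 0");
  Dpll s(nvars);
  for (R_xlen_t i = 0; i < clauses.size(); ++i) {
    IntegerVector cl = clauses[i];
    std::vector<int> lits(cl.begin(), cl.end());
    for (size_t k = 0; k < lits.size(); ++k) {
      int v = std::abs(lits[k]);
      if (v < 1 || v > nvars) stop("literal references unknown variable");
    }
    s.add_clause(lits);
  }
  std::vector<int> proj(project.begin(), project.end());
  List out;
  int found = 0;
  while (found < limit) {
    if (!s.solve()) break;
    IntegerVector m(nvars);
    for (int v = 1; v <= nvars; ++v) m[v - 1] = (s.val[v] == 1) ? 1 : 0;
    out.push_back(m);
    ++found;
    std::vector<int> block;
    for (size_t k = 0; k < proj.size(); ++k)
      if (s.val[proj[k]] == 1) block.push_back(-proj[k]);
    if (block.empty()) break; // nothing to block on: one solution class
    s.add_clause(block);
  }
  return out;
}
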