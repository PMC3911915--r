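#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler update of compartmental tubulin quantities on a rooted tree.
//
// The linear system (I - dt*M) Q_new = Q_old couples each compartment only to
// its parent and children, so Gaussian elimination in reverse breadth-first
// order (children before parents) produces no fill-in and runs in O(n).
//
// parent : 0-based parent index per compartment, -1 for the root (soma).
// g      : diffusive exchange coefficient with the parent, m^3/s
//          (diffusive flux child<-parent = g * (C_parent - C_child)).
// adv    : anterograde advective coefficient, m^3/s
//          (advective flux into compartment i from its parent = adv[i] * C_parent).
// vol    : compartment volumes, m^3.
// b      : first-order decay rate, 1/s (not applied to a clamped root).
// dt     : time step, s.
// q0     : tubulin quantities at the start of the step, mol.
// clamp_root : if true the root row is the Dirichlet condition Q_root = root_value.
// root_value : clamped root quantity (C_soma * V_soma), mol.
// [[Rcpp::export]]
NumericVector be_transport_step(IntegerVector parent, NumericVector g,
                                NumericVector adv, NumericVector vol,
                                double b, double dt, NumericVector q0,
                                bool clamp_root, double root_value) {
  const int n = parent.size();
  NumericVector diag(n), low(n), up(n), rhs(n), x(n);
  std::vector<int> order(n);
  int root = -1;

  // breadth-first order so that parents always precede children
  {
    std::vector<std::vector<int> > kids(n);
    for (int i = 0; i < n; ++i) {
      if (parent[i] < 0) root = i; else kids[parent[i]].push_back(i);
    }
    if (root < 0) stop("tree has no root");
    int head = 0, tail = 0;
    order[tail++] = root;
    while (head < tail) {
      int u = order[head++];
      for (size_t k = 0; k < kids[u].size(); ++k) order[tail++] = kids[u][k];
    }
    if (tail != n) stop("tree is disconnected or contains a cycle");
  }

  // assemble rows: diag, coupling to parent (low, in own row) and the
  // coefficient this node contributes to its parent's row (up)
  for (int i = 0; i < n; ++i) {
    diag[i] = 1.0 + dt * b;
    rhs[i]  = q0[i];
  }
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p < 0) continue;
    diag[i] += dt * g[i] / vol[i];
    low[i]   = -dt * (g[i] + adv[i]) / vol[p];
    up[i]    = -dt * g[i] / vol[i];
    diag[p] += dt * (g[i] + adv[i]) / vol[p];
  }
  if (clamp_root) {
    diag[root] = 1.0;
    rhs[root]  = root_value;
  }

  // eliminate leaves upward
  for (int k = n - 1; k >= 1; --k) {
    int i = order[k];
    int p = parent[i];
    if (clamp_root && p == root) continue;  // root row is fixed
    double f = up[i] / diag[i];
    diag[p] -= f * low[i];
    rhs[p]  -= f * rhs[i];
  }

  x[root] = rhs[root] / diag[root];
  for (int k = 1; k < n; ++k) {
    int i = order[k];
    x[i] = (rhs[i] - low[i] * x[parent[i]]) / diag[i];
  }
  return x;
}
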