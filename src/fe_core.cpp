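// Finite-element kernels for the dermal compression model.
//
// Units are the consistent micrometre system: lengths in um, elastic moduli
// in MPa, forces in uN (1 MPa * um^2 = 1 uN).
//
// Matrix: 4-node linear tetrahedra, total-Lagrangian Saint Venant-Kirchhoff:
//   E = (F'F - I)/2,  S = lambda tr(E) I + 2 mu E,  W = lambda/2 tr(E)^2 + mu E:E
// Fibers: 2-node circular-section beams; geometrically exact axial response on
// the current chord (engineering strain) plus linearized Euler-Bernoulli
// bending and torsion in the element's initial local frame. Internal forces
// are exact gradients of the element energies, so the assembled force is the
// gradient of the total strain energy.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Trip { std::vector<int> i, j; std::vector<double> x; };

static inline void add(Trip& T, int i, int j, double v) {
  T.i.push_back(i); T.j.push_back(j); T.x.push_back(v);
}

// ---------------------------------------------------------------------------
// SVK tetrahedra
// ---------------------------------------------------------------------------

// nodes0: n x 3 reference coordinates; tets: m x 4 (0-based); u: 3n
// (x,y,z interleaved per node). Returns internal force, energy, per-element
// equivalent Green-Lagrange strain, and (optionally) tangent triplets.
// [[Rcpp::export]]
List cpp_tet_assemble(NumericMatrix nodes0, IntegerMatrix tets,
                      double lambda, double mu, NumericVector u,
                      bool want_tangent) {
  const int m = tets.nrow();
  const int ndof = nodes0.nrow() * 3;
  NumericVector f(ndof);
  NumericVector eqstrain(m);
  double energy = 0.0;
  Trip T;
  if (want_tangent) { T.i.reserve((size_t)m * 144); T.j.reserve((size_t)m * 144); T.x.reserve((size_t)m * 144); }

  for (int e = 0; e < m; ++e) {
    int n0 = tets(e,0), n1 = tets(e,1), n2 = tets(e,2), n3 = tets(e,3);
    double X0[3], D[3][3];
    for (int c = 0; c < 3; ++c) {
      X0[c] = nodes0(n0, c);
      D[c][0] = nodes0(n1, c) - X0[c];
      D[c][1] = nodes0(n2, c) - X0[c];
      D[c][2] = nodes0(n3, c) - X0[c];
    }
    double det =
      D[0][0]*(D[1][1]*D[2][2]-D[1][2]*D[2][1]) -
      D[0][1]*(D[1][0]*D[2][2]-D[1][2]*D[2][0]) +
      D[0][2]*(D[1][0]*D[2][1]-D[1][1]*D[2][0]);
    double V0 = det / 6.0;
    if (V0 <= 0) stop("tetrahedron %d has non-positive reference volume", e + 1);
    // inverse of D
    double Di[3][3];
    Di[0][0] =  (D[1][1]*D[2][2]-D[1][2]*D[2][1]) / det;
    Di[0][1] = -(D[0][1]*D[2][2]-D[0][2]*D[2][1]) / det;
    Di[0][2] =  (D[0][1]*D[1][2]-D[0][2]*D[1][1]) / det;
    Di[1][0] = -(D[1][0]*D[2][2]-D[1][2]*D[2][0]) / det;
    Di[1][1] =  (D[0][0]*D[2][2]-D[0][2]*D[2][0]) / det;
    Di[1][2] = -(D[0][0]*D[1][2]-D[0][2]*D[1][0]) / det;
    Di[2][0] =  (D[1][0]*D[2][1]-D[1][1]*D[2][0]) / det;
    Di[2][1] = -(D[0][0]*D[2][1]-D[0][1]*D[2][0]) / det;
    Di[2][2] =  (D[0][0]*D[1][1]-D[0][1]*D[1][0]) / det;
    // shape gradients g[a][.] for a = 0..3 (g_a = grad N_a)
    double g[4][3];
    for (int c = 0; c < 3; ++c) {
      g[1][c] = Di[0][c]; g[2][c] = Di[1][c]; g[3][c] = Di[2][c];
      g[0][c] = -(g[1][c] + g[2][c] + g[3][c]);
    }
    int nd[4] = {n0, n1, n2, n3};
    // deformation gradient F = I + sum_a u_a (x) g_a
    double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 4; ++a) {
      for (int r = 0; r < 3; ++r) {
        double ua = u[3 * nd[a] + r];
        for (int c = 0; c < 3; ++c) F[r][c] += ua * g[a][c];
      }
    }
    double detF =
      F[0][0]*(F[1][1]*F[2][2]-F[1][2]*F[2][1]) -
      F[0][1]*(F[1][0]*F[2][2]-F[1][2]*F[2][0]) +
      F[0][2]*(F[1][0]*F[2][1]-F[1][1]*F[2][0]);
    if (detF <= 0) stop("element %d inverted (det F <= 0): load increment too large", e + 1);
    // E = (F'F - I)/2, S = lambda tr(E) I + 2 mu E
    double Ee[3][3], S[3][3];
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int t = 0; t < 3; ++t) s += F[t][r] * F[t][c];
      Ee[r][c] = 0.5 * (s - (r == c ? 1.0 : 0.0));
    }
    double trE = Ee[0][0] + Ee[1][1] + Ee[2][2];
    double EE = 0;
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) EE += Ee[r][c] * Ee[r][c];
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c)
      S[r][c] = 2.0 * mu * Ee[r][c] + (r == c ? lambda * trE : 0.0);
    energy += V0 * (0.5 * lambda * trE * trE + mu * EE);
    // equivalent strain of the deviator: sqrt(2/3 * dev(E):dev(E))
    double devEE = 0;
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
      double d = Ee[r][c] - (r == c ? trE / 3.0 : 0.0);
      devEE += d * d;
    }
    eqstrain[e] = std::sqrt(2.0 / 3.0 * devEE);
    // nodal forces f_a = V0 * P g_a with P = F S
    double P[3][3];
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int t = 0; t < 3; ++t) s += F[r][t] * S[t][c];
      P[r][c] = s;
    }
    double h[4][3]; // h_a = F g_a
    for (int a = 0; a < 4; ++a) for (int r = 0; r < 3; ++r) {
      double s = 0;
      for (int c = 0; c < 3; ++c) s += F[r][c] * g[a][c];
      h[a][r] = s;
    }
    for (int a = 0; a < 4; ++a) {
      for (int r = 0; r < 3; ++r) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += P[r][c] * g[a][c];
        f[3 * nd[a] + r] += V0 * s;
      }
    }
    if (want_tangent) {
      // B = F F'
      double B[3][3];
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
        double s = 0;
        for (int t = 0; t < 3; ++t) s += F[r][t] * F[c][t];
        B[r][c] = s;
      }
      for (int a = 0; a < 4; ++a) {
        for (int b = 0; b < 4; ++b) {
          // gSg = g_a' S g_b ; gg = g_a . g_b
          double gSg = 0, gg = 0;
          for (int r = 0; r < 3; ++r) {
            gg += g[a][r] * g[b][r];
            for (int c = 0; c < 3; ++c) gSg += g[a][r] * S[r][c] * g[b][c];
          }
          for (int i = 0; i < 3; ++i) for (int k = 0; k < 3; ++k) {
            double v = (i == k ? gSg : 0.0)
              + lambda * h[a][i] * h[b][k]
              + mu * h[b][i] * h[a][k]
              + mu * gg * B[i][k];
            add(T, 3 * nd[a] + i, 3 * nd[b] + k, V0 * v);
          }
        }
      }
    }
  }
  List out = List::create(_["f"] = f, _["energy"] = energy, _["eqstrain"] = eqstrain);
  if (want_tangent) {
    out["ki"] = IntegerVector(T.i.begin(), T.i.end());
    out["kj"] = IntegerVector(T.j.begin(), T.j.end());
    out["kx"] = NumericVector(T.x.begin(), T.x.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// beams
// ---------------------------------------------------------------------------

// local Euler-Bernoulli 12x12 stiffness WITHOUT the axial rows (axial handled
// nonlinearly); dof order per node: [ux uy uz rx ry rz] in the local frame
// with x the beam axis.
static void beam_local_bt(double E, double G, double L, double I, double J,
                          double K[12][12]) {
  for (int r = 0; r < 12; ++r) for (int c = 0; c < 12; ++c) K[r][c] = 0;
  double a = 12 * E * I / (L * L * L);
  double b = 6 * E * I / (L * L);
  double c4 = 4 * E * I / L;
  double c2 = 2 * E * I / L;
  double t = G * J / L;
  // bending in local x-y plane (uy, rz): dofs 1,5,7,11
  int iy[4] = {1, 5, 7, 11};
  double Ky[4][4] = {
    { a,  b, -a,  b},
    { b, c4, -b, c2},
    {-a, -b,  a, -b},
    { b, c2, -b, c4}};
  for (int r = 0; r < 4; ++r) for (int c = 0; c < 4; ++c) K[iy[r]][iy[c]] += Ky[r][c];
  // bending in local x-z plane (uz, ry): dofs 2,4,8,10 (note sign convention)
  int iz[4] = {2, 4, 8, 10};
  double Kz[4][4] = {
    { a, -b, -a, -b},
    {-b, c4,  b, c2},
    {-a,  b,  a,  b},
    {-b, c2,  b, c4}};
  for (int r = 0; r < 4; ++r) for (int c = 0; c < 4; ++c) K[iz[r]][iz[c]] += Kz[r][c];
  // torsion (rx): dofs 3, 9
  K[3][3] += t; K[9][9] += t; K[3][9] -= t; K[9][3] -= t;
}

// deterministic orthonormal frame with e1 = axis
static void beam_frame(const double* ax, double R[3][3]) {
  double L = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
  double e1[3] = {ax[0]/L, ax[1]/L, ax[2]/L};
  // pick the global axis least aligned with e1
  double ref[3] = {0, 0, 0};
  int imin = 0;
  for (int c = 1; c < 3; ++c) if (std::fabs(e1[c]) < std::fabs(e1[imin])) imin = c;
  ref[imin] = 1.0;
  double e2[3];
  double d = ref[0]*e1[0] + ref[1]*e1[1] + ref[2]*e1[2];
  for (int c = 0; c < 3; ++c) e2[c] = ref[c] - d * e1[c];
  double n2 = std::sqrt(e2[0]*e2[0] + e2[1]*e2[1] + e2[2]*e2[2]);
  for (int c = 0; c < 3; ++c) e2[c] /= n2;
  double e3[3] = {
    e1[1]*e2[2] - e1[2]*e2[1],
    e1[2]*e2[0] - e1[0]*e2[2],
    e1[0]*e2[1] - e1[1]*e2[0]};
  for (int c = 0; c < 3; ++c) { R[0][c] = e1[c]; R[1][c] = e2[c]; R[2][c] = e3[c]; }
}

// nodes0: matrix mesh nodes (translations shared); beams reference those node
// ids (0-based); rotations are beam-only dofs addressed through rot1/rot2
// (0-based slots). u: 3*nnodes translations, urot: 3*nrot rotations.
// Global dof ids for the tangent: translations 3*node+c, rotations
// 3*nnodes + 3*rotslot + c.
// [[Rcpp::export]]
List cpp_beam_assemble(NumericMatrix nodes0,
                       IntegerVector bn1, IntegerVector bn2,
                       IntegerVector rot1, IntegerVector rot2,
                       NumericVector diameter,
                       double E, double nu,
                       NumericVector u, NumericVector urot,
                       bool want_tangent) {
  const int nb = bn1.size();
  const int ntrans = nodes0.nrow() * 3;
  const int ndof = ntrans + urot.size();
  const double G = E / (2.0 * (1.0 + nu));
  NumericVector f(ndof);
  NumericVector axial(nb);
  double energy = 0.0;
  Trip T;
  if (want_tangent) { T.i.reserve((size_t)nb * 144); T.j.reserve((size_t)nb * 144); T.x.reserve((size_t)nb * 144); }

  for (int e = 0; e < nb; ++e) {
    int n1 = bn1[e], n2 = bn2[e];
    double X1[3], X2[3], ax[3];
    for (int c = 0; c < 3; ++c) {
      X1[c] = nodes0(n1, c); X2[c] = nodes0(n2, c);
      ax[c] = X2[c] - X1[c];
    }
    double L0 = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
    if (L0 <= 0) stop("beam %d has zero reference length", e + 1);
    double d = diameter[e];
    double A = M_PI * d * d / 4.0;
    double I = M_PI * d * d * d * d / 64.0;
    double J = 2.0 * I;
    // element dof gather: [u1 th1 u2 th2]
    int gdof[12];
    for (int c = 0; c < 3; ++c) {
      gdof[c]     = 3 * n1 + c;
      gdof[3 + c] = ntrans + 3 * rot1[e] + c;
      gdof[6 + c] = 3 * n2 + c;
      gdof[9 + c] = ntrans + 3 * rot2[e] + c;
    }
    double de[12];
    for (int c = 0; c < 3; ++c) {
      de[c]     = u[3 * n1 + c];
      de[3 + c] = urot[3 * rot1[e] + c];
      de[6 + c] = u[3 * n2 + c];
      de[9 + c] = urot[3 * rot2[e] + c];
    }
    // ---- nonlinear axial part (current chord) ----
    double x1[3], x2[3], ch[3];
    for (int c = 0; c < 3; ++c) {
      x1[c] = X1[c] + de[c]; x2[c] = X2[c] + de[6 + c];
      ch[c] = x2[c] - x1[c];
    }
    double L = std::sqrt(ch[0]*ch[0] + ch[1]*ch[1] + ch[2]*ch[2]);
    if (L <= 1e-12) stop("beam %d collapsed to zero current length", e + 1);
    double tdir[3] = {ch[0]/L, ch[1]/L, ch[2]/L};
    double eps = (L - L0) / L0;
    double N = E * A * eps;
    axial[e] = N;
    energy += 0.5 * E * A * L0 * eps * eps;
    for (int c = 0; c < 3; ++c) {
      f[3 * n1 + c] += -N * tdir[c];
      f[3 * n2 + c] +=  N * tdir[c];
    }
    // ---- linearized bending + torsion in the initial frame ----
    double R[3][3];
    beam_frame(ax, R);
    double Kl[12][12];
    beam_local_bt(E, G, L0, I, J, Kl);
    // Kg = Tt Kl T with T block-diagonal in R (4 blocks)
    double Tm[12][12] = {{0}};
    for (int blk = 0; blk < 4; ++blk)
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c)
        Tm[3 * blk + r][3 * blk + c] = R[r][c];
    double KT[12][12], Kg[12][12];
    for (int r = 0; r < 12; ++r) for (int c = 0; c < 12; ++c) {
      double s = 0;
      for (int t = 0; t < 12; ++t) s += Kl[r][t] * Tm[t][c];
      KT[r][c] = s;
    }
    for (int r = 0; r < 12; ++r) for (int c = 0; c < 12; ++c) {
      double s = 0;
      for (int t = 0; t < 12; ++t) s += Tm[t][r] * KT[t][c];
      Kg[r][c] = s;
    }
    double fb[12];
    double wb = 0;
    for (int r = 0; r < 12; ++r) {
      double s = 0;
      for (int c = 0; c < 12; ++c) s += Kg[r][c] * de[c];
      fb[r] = s;
      wb += 0.5 * de[r] * s;
    }
    energy += wb;
    for (int r = 0; r < 12; ++r) f[gdof[r]] += fb[r];
    if (want_tangent) {
      // axial tangent: EA/L0 t t' + N/L (I - t t') on translational blocks.
      // The geometric (N/L) part is applied tension-only: for compressed
      // fibers it is destabilizing (Euler buckling of the linearized beam)
      // and can make the tangent singular; dropping it keeps the tangent
      // positive semi-definite while the internal force - and therefore the
      // converged equilibrium - stays exact (an inexact-Jacobian Newton).
      double Ngeo = N > 0.0 ? N : 0.0;
      double Ka[3][3];
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
        double tt = tdir[r] * tdir[c];
        Ka[r][c] = (E * A / L0) * tt + (Ngeo / L) * ((r == c ? 1.0 : 0.0) - tt);
      }
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) {
        double v = Ka[r][c];
        add(T, 3*n1+r, 3*n1+c,  v);
        add(T, 3*n2+r, 3*n2+c,  v);
        add(T, 3*n1+r, 3*n2+c, -v);
        add(T, 3*n2+r, 3*n1+c, -v);
      }
      for (int r = 0; r < 12; ++r) for (int c = 0; c < 12; ++c)
        if (Kg[r][c] != 0) add(T, gdof[r], gdof[c], Kg[r][c]);
    }
  }
  List out = List::create(_["f"] = f, _["energy"] = energy, _["axial"] = axial);
  if (want_tangent) {
    out["ki"] = IntegerVector(T.i.begin(), T.i.end());
    out["kj"] = IntegerVector(T.j.begin(), T.j.end());
    out["kx"] = NumericVector(T.x.begin(), T.x.end());
  }
  return out;
}

// accumulate triplet values into slots (0 slots are dropped); map is 1-based,
// 0 = eliminated
// [[Rcpp::export]]
NumericVector cpp_accumulate(NumericVector x, IntegerVector map, int nslots) {
  NumericVector out(nslots);
  for (R_xlen_t t = 0; t < x.size(); ++t) {
    int s = map[t];
    if (s > 0) out[s - 1] += x[t];
  }
  return out;
}
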