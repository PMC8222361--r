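#include <Rcpp.h>
using namespace Rcpp;

// Tetrahedral element stiffness assembly and strain recovery.
//
// Elements are 4-node (constant-strain) or 10-node (quadratic) tetrahedra.
// Node ordering for the 10-node element follows the VTK quadratic tetra:
// vertices 1-4, then midside nodes on edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4).
// Midside nodes sit at edge midpoints, so the isoparametric Jacobian is the
// constant vertex Jacobian.
//
// Strain components are Voigt-ordered (exx, eyy, ezz, gxy, gyz, gzx) with
// engineering shear strains.

static const double GA = 0.5854101966249685; // 4-pt Gauss rule on the tet
static const double GB = 0.1381966011250105;

// dN/dxi for tet10 at barycentric point (L1,L2,L3,L4); xi = (L2,L3,L4).
static void tet10_dN(const double L[4], double dN[10][3]) {
  // dL/dxi rows: L1 -> (-1,-1,-1), L2 -> (1,0,0), L3 -> (0,1,0), L4 -> (0,0,1)
  const double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  const int edge[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int i = 0; i < 4; i++)
    for (int k = 0; k < 3; k++) dN[i][k] = (4.0 * L[i] - 1.0) * dL[i][k];
  for (int e = 0; e < 6; e++) {
    int a = edge[e][0], b = edge[e][1];
    for (int k = 0; k < 3; k++)
      dN[4 + e][k] = 4.0 * (L[a] * dL[b][k] + L[b] * dL[a][k]);
  }
}

// invert 3x3, returns det
static double inv3(const double J[3][3], double Ji[3][3]) {
  double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
               J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
               J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  double id = 1.0 / det;
  Ji[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
  Ji[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) * id;
  Ji[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
  Ji[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) * id;
  Ji[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
  Ji[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) * id;
  Ji[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
  Ji[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) * id;
  Ji[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
  return det;
}

// Fill B (6 x 3*nn) from spatial shape gradients g (nn x 3)
static void fill_B(int nn, const double g[][3], double *B) {
  int ncol = 3 * nn;
  for (int i = 0; i < 6 * ncol; i++) B[i] = 0.0;
  for (int a = 0; a < nn; a++) {
    int cx = 3 * a, cy = 3 * a + 1, cz = 3 * a + 2;
    B[0 * ncol + cx] = g[a][0];
    B[1 * ncol + cy] = g[a][1];
    B[2 * ncol + cz] = g[a][2];
    B[3 * ncol + cx] = g[a][1];
    B[3 * ncol + cy] = g[a][0];
    B[4 * ncol + cy] = g[a][2];
    B[4 * ncol + cz] = g[a][1];
    B[5 * ncol + cx] = g[a][2];
    B[5 * ncol + cz] = g[a][0];
  }
}

// [[Rcpp::export]]
List assemble_tets_cpp(NumericMatrix coords, IntegerMatrix elems,
                       NumericMatrix Dmats, IntegerVector mat_index) {
  int ne = elems.nrow(), nn = elems.ncol();
  if (nn != 4 && nn != 10) stop("elements must have 4 or 10 nodes");
  int ndof = 3 * nn;
  R_xlen_t nnz = (R_xlen_t)ne * ndof * ndof;
  IntegerVector iv((R_xlen_t)nnz), jv((R_xlen_t)nnz);
  NumericVector xv((R_xlen_t)nnz);

  int nqp = (nn == 4) ? 1 : 4;
  double qp[4][4]; // barycentric coords of quadrature points
  if (nn == 4) {
    qp[0][0] = qp[0][1] = qp[0][2] = qp[0][3] = 0.25;
  } else {
    for (int q = 0; q < 4; q++)
      for (int i = 0; i < 4; i++) qp[q][i] = (q == i) ? GA : GB;
  }

  std::vector<double> B(6 * ndof), DB(6 * ndof), Ke(ndof * ndof);
  double g[10][3], dN[10][3];

  for (int e = 0; e < ne; e++) {
    // constant Jacobian from vertices
    double J[3][3], Ji[3][3];
    int v0 = elems(e, 0) - 1;
    for (int c = 0; c < 3; c++) {
      J[0][c] = coords(elems(e, 1) - 1, c) - coords(v0, c);
      J[1][c] = coords(elems(e, 2) - 1, c) - coords(v0, c);
      J[2][c] = coords(elems(e, 3) - 1, c) - coords(v0, c);
    }
    // rows of J are dx/dxi_k => grad_x N = Ji^T? We use x = x0 + xi * J
    // (xi row vector), so dx_c/dxi_k = J[k][c]; grad_x N = Jinv applied:
    // dN/dx_c = sum_k dN/dxi_k * dxi_k/dx_c, with dxi/dx = inverse of dx/dxi.
    double det = inv3(J, Ji); // Ji = (dx/dxi)^{-1}: Ji[c][k] = dxi_k/dx_c? see below
    if (det <= 0) stop("inverted element (non-positive Jacobian) at element %d", e + 1);
    const double *D = &Dmats(0, 0) + (R_xlen_t)36 * (mat_index[e] - 1);

    std::fill(Ke.begin(), Ke.end(), 0.0);
    for (int q = 0; q < nqp; q++) {
      double w = det / 6.0 / nqp; // equal weights
      if (nn == 4) {
        // constant gradients: dN/dxi rows for (L1..L4)
        double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int a = 0; a < 4; a++)
          for (int c = 0; c < 3; c++) {
            g[a][c] = 0.0;
            for (int k = 0; k < 3; k++) g[a][c] += dL[a][k] * Ji[c][k];
          }
      } else {
        tet10_dN(qp[q], dN);
        for (int a = 0; a < 10; a++)
          for (int c = 0; c < 3; c++) {
            g[a][c] = 0.0;
            for (int k = 0; k < 3; k++) g[a][c] += dN[a][k] * Ji[c][k];
          }
      }
      fill_B(nn, g, B.data());
      // DB = D %*% B  (D is 6x6 column-major from R)
      for (int col = 0; col < ndof; col++)
        for (int r = 0; r < 6; r++) {
          double s = 0.0;
          for (int k = 0; k < 6; k++) s += D[r + 6 * k] * B[k * ndof + col];
          DB[r * ndof + col] = s;
        }
      // Ke += w * B^T DB
      for (int r = 0; r < ndof; r++)
        for (int c = 0; c < ndof; c++) {
          double s = 0.0;
          for (int k = 0; k < 6; k++) s += B[k * ndof + r] * DB[k * ndof + c];
          Ke[r * ndof + c] += w * s;
        }
    }
    // scatter triplets (1-based global dofs)
    R_xlen_t base = (R_xlen_t)e * ndof * ndof;
    for (int a = 0; a < nn; a++) {
      int ga = elems(e, a) - 1;
      for (int da = 0; da < 3; da++) {
        int row = 3 * ga + da + 1, lr = 3 * a + da;
        for (int b = 0; b < nn; b++) {
          int gb = elems(e, b) - 1;
          for (int db = 0; db < 3; db++) {
            R_xlen_t idx = base + (R_xlen_t)lr * ndof + 3 * b + db;
            iv[idx] = row;
            jv[idx] = 3 * gb + db + 1;
            xv[idx] = Ke[lr * ndof + (3 * b + db)];
          }
        }
      }
    }
  }
  return List::create(_["i"] = iv, _["j"] = jv, _["x"] = xv);
}

// Per-element strain recovery: centroid for tet4, average of the 4 Gauss
// points for tet10 (volume-weighted; weights equal). Returns ne x 6 Voigt.
// [[Rcpp::export]]
NumericMatrix element_strains_cpp(NumericMatrix coords, IntegerMatrix elems,
                                  NumericVector u) {
  int ne = elems.nrow(), nn = elems.ncol();
  NumericMatrix out(ne, 6);
  int nqp = (nn == 4) ? 1 : 4;
  double qp[4][4];
  if (nn == 4) {
    qp[0][0] = qp[0][1] = qp[0][2] = qp[0][3] = 0.25;
  } else {
    for (int q = 0; q < 4; q++)
      for (int i = 0; i < 4; i++) qp[q][i] = (q == i) ? GA : GB;
  }
  double g[10][3], dN[10][3];
  for (int e = 0; e < ne; e++) {
    double J[3][3], Ji[3][3];
    int v0 = elems(e, 0) - 1;
    for (int c = 0; c < 3; c++) {
      J[0][c] = coords(elems(e, 1) - 1, c) - coords(v0, c);
      J[1][c] = coords(elems(e, 2) - 1, c) - coords(v0, c);
      J[2][c] = coords(elems(e, 3) - 1, c) - coords(v0, c);
    }
    double det = inv3(J, Ji);
    if (det <= 0) stop("inverted element (non-positive Jacobian) at element %d", e + 1);
    double eps[6] = {0, 0, 0, 0, 0, 0};
    for (int q = 0; q < nqp; q++) {
      if (nn == 4) {
        double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int a = 0; a < 4; a++)
          for (int c = 0; c < 3; c++) {
            g[a][c] = 0.0;
            for (int k = 0; k < 3; k++) g[a][c] += dL[a][k] * Ji[c][k];
          }
      } else {
        tet10_dN(qp[q], dN);
        for (int a = 0; a < 10; a++)
          for (int c = 0; c < 3; c++) {
            g[a][c] = 0.0;
            for (int k = 0; k < 3; k++) g[a][c] += dN[a][k] * Ji[c][k];
          }
      }
      double du[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}}; // du_i/dx_j
      for (int a = 0; a < nn; a++) {
        int gn = elems(e, a) - 1;
        for (int i = 0; i < 3; i++)
          for (int c = 0; c < 3; c++) du[i][c] += u[3 * gn + i] * g[a][c];
      }
      eps[0] += du[0][0];
      eps[1] += du[1][1];
      eps[2] += du[2][2];
      eps[3] += du[0][1] + du[1][0];
      eps[4] += du[1][2] + du[2][1];
      eps[5] += du[2][0] + du[0][2];
    }
    for (int k = 0; k < 6; k++) out(e, k) = eps[k] / nqp;
  }
  return out;
}

// Signed element volumes (vertex tet formula; exact for straight-edged tet10).
// [[Rcpp::export]]
NumericVector element_volumes_cpp(NumericMatrix coords, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericVector v(ne);
  for (int e = 0; e < ne; e++) {
    double J[3][3];
    int v0 = elems(e, 0) - 1;
    for (int c = 0; c < 3; c++) {
      J[0][c] = coords(elems(e, 1) - 1, c) - coords(v0, c);
      J[1][c] = coords(elems(e, 2) - 1, c) - coords(v0, c);
      J[2][c] = coords(elems(e, 3) - 1, c) - coords(v0, c);
    }
    double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                 J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                 J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    v[e] = det / 6.0;
  }
  return v;
}
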