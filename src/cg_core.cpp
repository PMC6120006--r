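// Compiled core: multipolar pair-interaction kernel (energy, analytic force
// and torques from the moment-tensor series) and the rigid-body MD loop for
// both the coarse-grained and the all-atom-summation engines.
//
// Units: length A, time ps, mass amu, energy kcal/mol. Forces from the
// potential are converted to amu A/ps^2 with KCAL = 418.4.
//
// Tensor pack layout (flat, col-major within each block), length 135:
//   [0]       N            (Gamma(0))
//   [1..3]    g1           (Gamma(1))
//   [4..12]   G2           (Gamma(2), (i,j) at 4 + i + 3j)
//   [13]      t2           (Tr2 Gamma(2))
//   [14..16]  h3           (Tr2 Gamma(3))
//   [17..43]  G3           (Gamma(3), (i,j,k) at 17 + i + 3j + 9k)
//   [44]      tr4          (Tr4 Gamma(4))
//   [45..53]  H4           (Tr2 Gamma(4))
//   [54..134] G4           (Gamma(4), (i,j,k,l) at 54 + i + 3j + 9k + 27l)

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCAL = 418.4;          // kcal/mol -> amu A^2/ps^2
static const double KB_INT = 0.0019872041 * KCAL;  // amu A^2/ps^2 per K

// ---------------------------------------------------------------- potential

struct Pot {
  int kind;           // 0 morse, 1 lj
  double p1, p2, p3, p4;  // morse: De, alpha, R0 ; lj: eps, sigma, al, be
};

static Pot make_pot(const NumericVector& spec) {
  Pot p;
  p.kind = (int)spec[0];
  p.p1 = spec[1]; p.p2 = spec[2]; p.p3 = spec[3]; p.p4 = spec[4];
  return p;
}

// d^k U / dR^k
static double u_deriv(const Pot& p, double R, int k) {
  if (p.kind == 0) {
    double a = p.p2;
    double e2 = std::exp(-2.0 * a * (R - p.p3));
    double e1 = std::exp(-a * (R - p.p3));
    double s2 = 1.0, s1 = 1.0;
    for (int i = 0; i < k; ++i) { s2 *= -2.0 * a; s1 *= -a; }
    return p.p1 * (s2 * e2 - 2.0 * s1 * e1);
  } else {
    double al = p.p3, be = p.p4, s = p.p2;
    double fa = 1.0, fb = 1.0, sg = (k % 2 == 0) ? 1.0 : -1.0;
    for (int i = 0; i < k; ++i) { fa *= (al + i); fb *= (be + i); }
    return 4.0 * p.p1 * sg *
      (fa * std::pow(s / R, al) / std::pow(R, (double)k) -
       fb * std::pow(s / R, be) / std::pow(R, (double)k));
  }
}

// D_k = (1/R d/dR)^k U for k = 0..5 (coefficients (2j-1)!! pattern)
static void radial_operator_stack(const Pot& p, double R, double D[6]) {
  double U[6];
  for (int k = 0; k <= 5; ++k) U[k] = u_deriv(p, R, k);
  double iR = 1.0 / R;
  double iR2 = iR * iR, iR3 = iR2 * iR, iR4 = iR3 * iR, iR5 = iR4 * iR;
  D[0] = U[0];
  D[1] = U[1] * iR;
  D[2] = U[2] * iR2 - U[1] * iR3;
  D[3] = U[3] * iR3 - 3.0 * U[2] * iR4 + 3.0 * U[1] * iR5;
  D[4] = U[4] * iR4 - 6.0 * U[3] * iR5 + 15.0 * U[2] * iR4 * iR2
         - 15.0 * U[1] * iR5 * iR2;
  D[5] = U[5] * iR5 - 10.0 * U[4] * iR4 * iR2 + 45.0 * U[3] * iR5 * iR2
         - 105.0 * U[2] * iR4 * iR4 + 105.0 * U[1] * iR5 * iR4;
}

// nine (m, n) pairs in canonical order
static const int MN_M[9] = {0, 1, 2, 2, 3, 3, 4, 4, 4};
static const int MN_N[9] = {0, 1, 0, 2, 1, 3, 0, 2, 4};
static const double MN_C[9] = {1, 1, 2, 2, 2, 6, 8, 4, 24}; // n! (m-n)!!

// V(mn) and dV(mn)/dR for all nine index pairs
static void radial_coeffs(const Pot& p, double R, double V[9], double dV[9]) {
  double D[6];
  radial_operator_stack(p, R, D);
  for (int t = 0; t < 9; ++t) {
    int n = MN_N[t];
    int k = (MN_M[t] + n) / 2;
    double Rn = std::pow(R, (double)n);
    V[t] = Rn * D[k] / MN_C[t];
    dV[t] = (n * Rn / R * D[k] + Rn * R * D[k + 1]) / MN_C[t];
  }
}

// central-term shortcut: V(00) = U, dV(00) = U'
static void radial_coeffs0(const Pot& p, double R, double* V00, double* dV00) {
  *V00 = u_deriv(p, R, 0);
  *dV00 = u_deriv(p, R, 1);
}

// ------------------------------------------------------------ small algebra

static inline void cross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ------------------------------------------------------------- lab tensors

struct LabT {
  double N;
  double g1[3];
  double G2[9];     // (i,j) at i + 3j
  double t2;
  double h3[3];
  double G3[27];
  double tr4;
  double H4[9];
  double G4[81];
};

static void unpack(const double* p, LabT& T) {
  T.N = p[0];
  for (int i = 0; i < 3; ++i) T.g1[i] = p[1 + i];
  for (int i = 0; i < 9; ++i) T.G2[i] = p[4 + i];
  T.t2 = p[13];
  for (int i = 0; i < 3; ++i) T.h3[i] = p[14 + i];
  for (int i = 0; i < 27; ++i) T.G3[i] = p[17 + i];
  T.tr4 = p[44];
  for (int i = 0; i < 9; ++i) T.H4[i] = p[45 + i];
  for (int i = 0; i < 81; ++i) T.G4[i] = p[54 + i];
}

// quaternion (w,x,y,z) -> rotation matrix, row-major R[3][3]
static void quat_to_R(const double* q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// apply Q to the leading index of a rank-r tensor (col-major flat), then
// cyclically shift the index order; r applications transform every index
static void rotate_rank(const double Q[3][3], const double* in, double* out,
                        int rank, double* scratch) {
  int total = 1;
  for (int i = 0; i < rank; ++i) total *= 3;
  int rest = total / 3;
  // copy input into scratch
  double* cur = scratch;          // size total
  double* nxt = scratch + total;  // size total
  for (int i = 0; i < total; ++i) cur[i] = in[i];
  for (int round = 0; round < rank; ++round) {
    for (int r = 0; r < rest; ++r) {
      double a0 = cur[0 + 3 * r], a1 = cur[1 + 3 * r], a2 = cur[2 + 3 * r];
      double b0 = Q[0][0] * a0 + Q[0][1] * a1 + Q[0][2] * a2;
      double b1 = Q[1][0] * a0 + Q[1][1] * a1 + Q[1][2] * a2;
      double b2 = Q[2][0] * a0 + Q[2][1] * a1 + Q[2][2] * a2;
      // cyclic shift: new flat index of (i2..ir, i1) = r + rest * i1
      nxt[r + rest * 0] = b0;
      nxt[r + rest * 1] = b1;
      nxt[r + rest * 2] = b2;
    }
    double* tmp = cur; cur = nxt; nxt = tmp;
  }
  for (int i = 0; i < total; ++i) out[i] = cur[i];
}

// rotate only the ranks a truncation at max_m can touch
static void rotate_pack(const double Q[3][3], const LabT& body, LabT& lab,
                        int max_m = 4) {
  double scratch[162];
  lab.N = body.N; lab.t2 = body.t2; lab.tr4 = body.tr4;
  if (max_m >= 1) rotate_rank(Q, body.g1, lab.g1, 1, scratch);
  if (max_m >= 2) rotate_rank(Q, body.G2, lab.G2, 2, scratch);
  if (max_m >= 3) {
    rotate_rank(Q, body.h3, lab.h3, 1, scratch);
    rotate_rank(Q, body.G3, lab.G3, 3, scratch);
  }
  if (max_m >= 4) {
    rotate_rank(Q, body.H4, lab.H4, 2, scratch);
    rotate_rank(Q, body.G4, lab.G4, 4, scratch);
  }
}

// --------------------------------------------------------------- pair kernel

struct PairOut {
  double energy;
  double force[3];     // on A (lab)
  double tauA[3];      // torque on A about its center (lab)
  double tauB[3];
};

// matrix-vector, (i,j) at i+3j
static inline void mv(const double* M, const double* v, double* out) {
  out[0] = M[0] * v[0] + M[3] * v[1] + M[6] * v[2];
  out[1] = M[1] * v[0] + M[4] * v[1] + M[7] * v[2];
  out[2] = M[2] * v[0] + M[5] * v[1] + M[8] * v[2];
}

// contract rank-3 (flat) with two vectors on trailing indices: out_i = G3[i,j,k] a_j b_k
static inline void g3_contract2(const double* G3, const double* a,
                                const double* b, double* out) {
  for (int i = 0; i < 3; ++i) {
    double s = 0;
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        s += G3[i + 3 * j + 9 * k] * a[j] * b[k];
    out[i] = s;
  }
}

// out_i = G4[i,j,k,l] u_j u_k u_l
static inline void g4_contract3(const double* G4, const double* u, double* out) {
  for (int i = 0; i < 3; ++i) {
    double s = 0;
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) {
        double uu = u[j] * u[k];
        for (int l = 0; l < 3; ++l)
          s += G4[i + 3 * j + 9 * k + 27 * l] * uu * u[l];
      }
    out[i] = s;
  }
}

static void pair_kernel(const LabT& A, const LabT& B, const double* Rvec,
                        const Pot& pot, int max_m, double eshift,
                        PairOut& out) {
  double R = std::sqrt(dot3(Rvec, Rvec));
  double u[3] = {Rvec[0] / R, Rvec[1] / R, Rvec[2] / R};
  double NA_ = A.N, NB_ = B.N;

  if (max_m <= 0) {
    // central term only: V(00) Theta(00) = N_A N_B U(R)
    double V00, dV00;
    radial_coeffs0(pot, R, &V00, &dV00);
    out.energy = NA_ * NB_ * V00 - eshift;
    double f = -NA_ * NB_ * dV00;
    for (int i = 0; i < 3; ++i) {
      out.force[i] = f * u[i];
      out.tauA[i] = 0; out.tauB[i] = 0;
    }
    return;
  }

  double V[9], dV[9];
  radial_coeffs(pot, R, V, dV);

  // shared invariants (higher-rank groups computed only when retained)
  double q1A = dot3(A.g1, u), q1B = dot3(B.g1, u);
  double P11 = dot3(A.g1, B.g1);
  double G2Au[3] = {0, 0, 0}, G2Bu[3] = {0, 0, 0};
  double G2Ag1B[3] = {0, 0, 0}, G2Bg1A[3] = {0, 0, 0};
  double Q2A = 0, Q2B = 0, X2AB = 0, X2BA = 0;
  if (max_m >= 2) {
    mv(A.G2, u, G2Au); mv(B.G2, u, G2Bu);
    Q2A = dot3(u, G2Au); Q2B = dot3(u, G2Bu);
  }
  double h3A_R = 0, h3B_R = 0, h3A_g1B = 0, h3B_g1A = 0;
  double v3A[3] = {0, 0, 0}, v3B[3] = {0, 0, 0};
  double u3A[3] = {0, 0, 0}, u3B[3] = {0, 0, 0};
  double T3A = 0, T3B = 0, Z3A = 0, Z3B = 0;
  if (max_m >= 3) {
    mv(A.G2, B.g1, G2Ag1B); mv(B.G2, A.g1, G2Bg1A);
    X2AB = dot3(u, G2Ag1B); X2BA = dot3(u, G2Bg1A);
    h3A_R = dot3(A.h3, u); h3B_R = dot3(B.h3, u);
    h3A_g1B = dot3(A.h3, B.g1); h3B_g1A = dot3(B.h3, A.g1);
    g3_contract2(A.G3, u, u, v3A);
    g3_contract2(B.G3, u, u, v3B);
    g3_contract2(A.G3, u, B.g1, u3A);
    g3_contract2(B.G3, u, A.g1, u3B);
    T3A = dot3(v3A, u); T3B = dot3(v3B, u);
    Z3A = dot3(v3A, B.g1); Z3B = dot3(v3B, A.g1);
  }
  double C22 = 0, Y = 0, H4A_RR = 0, H4B_RR = 0, T4A = 0, T4B = 0;
  double K[9] = {0}, KABu[3] = {0, 0, 0}, KBAu[3] = {0, 0, 0};
  double axK[3] = {0, 0, 0};
  double H4Au[3] = {0, 0, 0}, H4Bu[3] = {0, 0, 0};
  double w4A[3] = {0, 0, 0}, w4B[3] = {0, 0, 0};
  if (max_m >= 4) {
    for (int i = 0; i < 9; ++i) C22 += A.G2[i] * B.G2[i];
    // K = G2A * G2B  (i,j) at i+3j
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += A.G2[i + 3 * k] * B.G2[k + 3 * j];
        K[i + 3 * j] = s;
      }
    mv(K, u, KABu);
    // K^T u
    KBAu[0] = K[0] * u[0] + K[1] * u[1] + K[2] * u[2];
    KBAu[1] = K[3] * u[0] + K[4] * u[1] + K[5] * u[2];
    KBAu[2] = K[6] * u[0] + K[7] * u[1] + K[8] * u[2];
    Y = dot3(u, KABu);
    axK[0] = K[1 + 3 * 2] - K[2 + 3 * 1];
    axK[1] = K[2 + 3 * 0] - K[0 + 3 * 2];
    axK[2] = K[0 + 3 * 1] - K[1 + 3 * 0];
    mv(A.H4, u, H4Au); mv(B.H4, u, H4Bu);
    H4A_RR = dot3(u, H4Au); H4B_RR = dot3(u, H4Bu);
    g4_contract3(A.G4, u, w4A);
    g4_contract3(B.G4, u, w4B);
    T4A = dot3(w4A, u); T4B = dot3(w4B, u);
  }

  // Theta values
  double Th[9];
  Th[0] = NA_ * NB_;
  Th[1] = NB_ * q1A - NA_ * q1B;
  Th[2] = NB_ * A.t2 + NA_ * B.t2 - 2 * P11;
  Th[3] = NB_ * Q2A + NA_ * Q2B - 2 * q1A * q1B;
  Th[4] = NB_ * h3A_R - NA_ * h3B_R + q1A * B.t2 - q1B * A.t2
          - 2 * X2AB + 2 * X2BA;
  Th[5] = NB_ * T3A - NA_ * T3B - 3 * Q2A * q1B + 3 * q1A * Q2B;
  Th[6] = NB_ * A.tr4 + NA_ * B.tr4 + 4 * C22 + 2 * A.t2 * B.t2
          - 4 * h3A_g1B - 4 * h3B_g1A;
  Th[7] = NB_ * H4A_RR + NA_ * H4B_RR + Q2A * B.t2 + A.t2 * Q2B + 4 * Y
          - 2 * Z3A - 2 * Z3B - 2 * h3A_R * q1B - 2 * q1A * h3B_R;
  Th[8] = NB_ * T4A + NA_ * T4B + 6 * Q2A * Q2B
          - 4 * T3A * q1B - 4 * q1A * T3B;

  // dTheta/du (unconstrained gradient wrt the unit vector)
  double G[9][3];
  for (int t = 0; t < 9; ++t) G[t][0] = G[t][1] = G[t][2] = 0;
  for (int i = 0; i < 3; ++i) {
    G[1][i] = NB_ * A.g1[i] - NA_ * B.g1[i];
    G[3][i] = 2 * NB_ * G2Au[i] + 2 * NA_ * G2Bu[i]
              - 2 * (q1B * A.g1[i] + q1A * B.g1[i]);
    G[4][i] = NB_ * A.h3[i] - NA_ * B.h3[i] + B.t2 * A.g1[i] - A.t2 * B.g1[i]
              - 2 * G2Ag1B[i] + 2 * G2Bg1A[i];
    G[5][i] = 3 * NB_ * v3A[i] - 3 * NA_ * v3B[i] - 6 * q1B * G2Au[i]
              - 3 * Q2A * B.g1[i] + 3 * Q2B * A.g1[i] + 6 * q1A * G2Bu[i];
    G[7][i] = 2 * NB_ * H4Au[i] + 2 * NA_ * H4Bu[i]
              + 2 * B.t2 * G2Au[i] + 2 * A.t2 * G2Bu[i]
              + 4 * (KABu[i] + KBAu[i]) - 4 * u3A[i] - 4 * u3B[i]
              - 2 * (q1B * A.h3[i] + h3A_R * B.g1[i])
              - 2 * (h3B_R * A.g1[i] + q1A * B.h3[i]);
    G[8][i] = 4 * NB_ * w4A[i] + 4 * NA_ * w4B[i]
              + 12 * (Q2B * G2Au[i] + Q2A * G2Bu[i])
              - 4 * (3 * q1B * v3A[i] + T3A * B.g1[i])
              - 4 * (T3B * A.g1[i] + 3 * q1A * v3B[i]);
  }

  // rotational gradients dTheta/dtheta_A and dTheta/dtheta_B
  double TA[9][3], TB[9][3];
  for (int t = 0; t < 9; ++t)
    for (int i = 0; i < 3; ++i) { TA[t][i] = 0; TB[t][i] = 0; }
  double c1[3], c2[3], c3[3], c4[3];

  cross(A.g1, u, c1);                       // g1A x u
  cross(B.g1, u, c2);                       // g1B x u
  double gAxgB[3]; cross(A.g1, B.g1, gAxgB);
  double G2AuXu[3]; cross(G2Au, u, G2AuXu);
  double G2BuXu[3]; cross(G2Bu, u, G2BuXu);

  for (int i = 0; i < 3; ++i) {
    TA[1][i] = NB_ * c1[i];
    TB[1][i] = -NA_ * c2[i];
    TA[2][i] = -2 * gAxgB[i];
    TB[2][i] = 2 * gAxgB[i];
    TA[3][i] = 2 * NB_ * G2AuXu[i] - 2 * q1B * c1[i];
    TB[3][i] = 2 * NA_ * G2BuXu[i] - 2 * q1A * c2[i];
  }
  // (3,1)
  cross(A.h3, u, c3); cross(B.h3, u, c4);
  {
    double a1[3], a2[3], b1[3], b2[3];
    cross(G2Ag1B, u, a1);                 // (G2A g1B) x u
    cross(G2Au, B.g1, a2);                // (G2A u) x g1B
    cross(A.g1, G2Bu, b1);                // g1A x (G2B u)
    cross(B.g1, G2Au, b2);                // g1B x (G2A u)
    double a3[3], a4[3];
    cross(G2Bg1A, u, a3);                 // (G2B g1A) x u
    cross(G2Bu, A.g1, a4);                // (G2B u) x g1A
    for (int i = 0; i < 3; ++i) {
      TA[4][i] = NB_ * c3[i] + B.t2 * c1[i]
                 - 2 * (a1[i] + a2[i]) + 2 * b1[i];
      TB[4][i] = -NA_ * c4[i] - A.t2 * c2[i]
                 - 2 * b2[i] + 2 * (a3[i] + a4[i]);
    }
  }
  // (3,3)
  {
    double v3AXu[3], v3BXu[3];
    cross(v3A, u, v3AXu); cross(v3B, u, v3BXu);
    for (int i = 0; i < 3; ++i) {
      TA[5][i] = 3 * NB_ * v3AXu[i] - 6 * q1B * G2AuXu[i] + 3 * Q2B * c1[i];
      TB[5][i] = -3 * NA_ * v3BXu[i] - 3 * Q2A * c2[i] + 6 * q1A * G2BuXu[i];
    }
  }
  // (4,0)
  {
    double h3AxgB[3], gAxh3B[3];
    cross(A.h3, B.g1, h3AxgB);
    cross(A.g1, B.h3, gAxh3B);
    for (int i = 0; i < 3; ++i) {
      TA[6][i] = 8 * axK[i] - 4 * h3AxgB[i] - 4 * gAxh3B[i];
      TB[6][i] = -8 * axK[i] + 4 * h3AxgB[i] + 4 * gAxh3B[i];
    }
  }
  // (4,2)
  {
    double H4AuXu[3], H4BuXu[3], KABuXu[3], KBAuXu[3];
    cross(H4Au, u, H4AuXu); cross(H4Bu, u, H4BuXu);
    cross(KABu, u, KABuXu); cross(KBAu, u, KBAuXu);
    double G2AuXG2Bu[3]; cross(G2Au, G2Bu, G2AuXG2Bu);
    double u3AXu[3], u3BXu[3];
    cross(u3A, u, u3AXu); cross(u3B, u, u3BXu);
    double v3AxgB[3], gAxv3B[3], gBxv3A[3], v3BxgA[3];
    cross(v3A, B.g1, v3AxgB);
    cross(A.g1, v3B, gAxv3B);
    cross(B.g1, v3A, gBxv3A);
    cross(v3B, A.g1, v3BxgA);
    for (int i = 0; i < 3; ++i) {
      TA[7][i] = 2 * NB_ * H4AuXu[i] + 2 * B.t2 * G2AuXu[i]
                 + 4 * (KABuXu[i] + G2AuXG2Bu[i])
                 - 4 * u3AXu[i] - 2 * v3AxgB[i] - 2 * gAxv3B[i]
                 - 2 * q1B * c3[i] - 2 * h3B_R * c1[i];
      TB[7][i] = 2 * NA_ * H4BuXu[i] + 2 * A.t2 * G2BuXu[i]
                 + 4 * (KBAuXu[i] - G2AuXG2Bu[i])
                 - 2 * gBxv3A[i] - 4 * u3BXu[i] - 2 * v3BxgA[i]
                 - 2 * q1A * c4[i] - 2 * h3A_R * c2[i];
    }
  }
  // (4,4)
  {
    double w4AXu[3], w4BXu[3], v3AXu[3], v3BXu[3];
    cross(w4A, u, w4AXu); cross(w4B, u, w4BXu);
    cross(v3A, u, v3AXu); cross(v3B, u, v3BXu);
    for (int i = 0; i < 3; ++i) {
      TA[8][i] = 4 * NB_ * w4AXu[i] + 12 * Q2B * G2AuXu[i]
                 - 12 * q1B * v3AXu[i] - 4 * T3B * c1[i];
      TB[8][i] = 4 * NA_ * w4BXu[i] + 12 * Q2A * G2BuXu[i]
                 - 12 * q1A * v3BXu[i] - 4 * T3A * c2[i];
    }
  }

  // assemble energy, force, torques over the retained terms
  double E = 0, Fsum = 0, Gsum[3] = {0, 0, 0};
  double tA[3] = {0, 0, 0}, tB[3] = {0, 0, 0};
  for (int t = 0; t < 9; ++t) {
    if (MN_M[t] > max_m) continue;
    E += V[t] * Th[t];
    Fsum += dV[t] * Th[t];
    for (int i = 0; i < 3; ++i) {
      Gsum[i] += V[t] * G[t][i];
      tA[i] += V[t] * TA[t][i];
      tB[i] += V[t] * TB[t][i];
    }
  }
  double gu = dot3(Gsum, u);
  for (int i = 0; i < 3; ++i) {
    out.force[i] = -Fsum * u[i] - (Gsum[i] - gu * u[i]) / R;
    out.tauA[i] = -tA[i];
    out.tauB[i] = -tB[i];
  }
  out.energy = E - eshift;
}

// [[Rcpp::export]]
List cg_pair_kernel_cpp(NumericVector packA, NumericVector packB,
                        NumericVector Rvec, NumericVector pot, int max_m) {
  LabT A, B;
  unpack(REAL(packA), A);
  unpack(REAL(packB), B);
  Pot p = make_pot(pot);
  double rv[3] = {Rvec[0], Rvec[1], Rvec[2]};
  PairOut out;
  pair_kernel(A, B, rv, p, max_m, 0.0, out);
  return List::create(
    _["energy"] = out.energy,
    _["force"] = NumericVector::create(out.force[0], out.force[1], out.force[2]),
    _["torque_A"] = NumericVector::create(out.tauA[0], out.tauA[1], out.tauA[2]),
    _["torque_B"] = NumericVector::create(out.tauB[0], out.tauB[1], out.tauB[2]));
}

// ------------------------------------------------------------------ MD loop

struct Forces {
  std::vector<double> F;     // 3N, amu A/ps^2 NOT converted (kcal/mol/A)
  std::vector<double> tau;   // 3N lab torques (kcal/mol)
  double pe;                 // kcal/mol
};

static inline void min_image(double* d, double box) {
  if (box > 0)
    for (int k = 0; k < 3; ++k) d[k] -= box * std::nearbyint(d[k] / box);
}

// CG engine force evaluation
static void eval_forces_cg(const std::vector<double>& pos,
                           const std::vector<LabT>& lab,
                           double box, const Pot& pot, int max_m,
                           double cutoff, double eshift, int N,
                           Forces& out) {
  std::fill(out.F.begin(), out.F.end(), 0.0);
  std::fill(out.tau.begin(), out.tau.end(), 0.0);
  out.pe = 0;
  double rc2 = (cutoff > 0) ? cutoff * cutoff : -1.0;
  PairOut po;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d[3] = {pos[3 * i] - pos[3 * j],
                     pos[3 * i + 1] - pos[3 * j + 1],
                     pos[3 * i + 2] - pos[3 * j + 2]};
      min_image(d, box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (rc2 > 0 && r2 > rc2) continue;
      pair_kernel(lab[i], lab[j], d, pot, max_m, eshift, po);
      out.pe += po.energy;
      for (int k = 0; k < 3; ++k) {
        out.F[3 * i + k] += po.force[k];
        out.F[3 * j + k] -= po.force[k];
        out.tau[3 * i + k] += po.tauA[k];
        out.tau[3 * j + k] += po.tauB[k];
      }
    }
  }
}

// all-atom engine force evaluation (exact double sum over atoms)
static void eval_forces_allatom(const std::vector<double>& pos,
                                const std::vector<double>& atoms_lab,
                                int natoms, double box, const Pot& pot,
                                double cutoff, int N, Forces& out) {
  std::fill(out.F.begin(), out.F.end(), 0.0);
  std::fill(out.tau.begin(), out.tau.end(), 0.0);
  out.pe = 0;
  double rc2 = (cutoff > 0) ? cutoff * cutoff : -1.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d[3] = {pos[3 * i] - pos[3 * j],
                     pos[3 * i + 1] - pos[3 * j + 1],
                     pos[3 * i + 2] - pos[3 * j + 2]};
      min_image(d, box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (rc2 > 0 && r2 > rc2) continue;
      const double* ra = &atoms_lab[3 * natoms * i];
      const double* rb = &atoms_lab[3 * natoms * j];
      for (int a = 0; a < natoms; ++a) {
        for (int b = 0; b < natoms; ++b) {
          double v[3] = {d[0] + ra[3 * a] - rb[3 * b],
                         d[1] + ra[3 * a + 1] - rb[3 * b + 1],
                         d[2] + ra[3 * a + 2] - rb[3 * b + 2]};
          double r = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
          out.pe += u_deriv(pot, r, 0);
          double fmag = -u_deriv(pot, r, 1) / r;   // f = fmag * v acts on i
          double f[3] = {fmag * v[0], fmag * v[1], fmag * v[2]};
          double ta[3], tb[3];
          cross(&ra[3 * a], f, ta);
          cross(&rb[3 * b], f, tb);
          for (int k = 0; k < 3; ++k) {
            out.F[3 * i + k] += f[k];
            out.F[3 * j + k] -= f[k];
            out.tau[3 * i + k] += ta[k];
            out.tau[3 * j + k] -= tb[k];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List md_run_cpp(int engine, NumericVector body_pack, NumericMatrix atoms_body,
                double mass, NumericVector inertia,
                NumericMatrix pos0, NumericMatrix vel0, NumericMatrix quat0,
                NumericMatrix omega0,
                double box, NumericVector pot_spec, int max_m,
                double cutoff, bool shift,
                double dt, int n_steps, double t_target, int thermo_interval,
                int pos_stride, int vel_stride, int log_stride) {
  const int N = pos0.nrow();
  const int natoms = atoms_body.nrow();
  Pot pot = make_pot(pot_spec);
  LabT body;
  unpack(REAL(body_pack), body);

  double eshift = 0.0;
  if (shift && cutoff > 0 && engine == 0)
    eshift = body.N * body.N * u_deriv(pot, cutoff, 0);

  // state
  std::vector<double> pos(3 * N), vel(3 * N), quat(4 * N), om(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      pos[3 * i + k] = pos0(i, k);
      vel[3 * i + k] = vel0(i, k);
      om[3 * i + k] = omega0(i, k);
    }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 4; ++k) quat[4 * i + k] = quat0(i, k);

  double I1 = inertia[0], I2 = inertia[1], I3 = inertia[2];

  std::vector<LabT> lab(N);
  std::vector<double> atoms_lab;   // N * natoms * 3
  if (engine == 1) atoms_lab.resize(3 * natoms * N);

  // template body atom coords (flat, atom-major)
  std::vector<double> abody(3 * natoms);
  for (int a = 0; a < natoms; ++a)
    for (int k = 0; k < 3; ++k) abody[3 * a + k] = atoms_body(a, k);

  auto refresh_orientation_caches = [&]() {
    double Q[3][3];
    for (int i = 0; i < N; ++i) {
      quat_to_R(&quat[4 * i], Q);
      if (engine == 0) {
        rotate_pack(Q, body, lab[i], max_m);
      } else {
        for (int a = 0; a < natoms; ++a) {
          double* o = &atoms_lab[3 * natoms * i + 3 * a];
          const double* v = &abody[3 * a];
          for (int r = 0; r < 3; ++r)
            o[r] = Q[r][0] * v[0] + Q[r][1] * v[1] + Q[r][2] * v[2];
        }
      }
    }
  };

  Forces frc;
  frc.F.resize(3 * N); frc.tau.resize(3 * N);
  auto eval = [&]() {
    if (engine == 0)
      eval_forces_cg(pos, lab, box, pot, max_m, cutoff, eshift, N, frc);
    else
      eval_forces_allatom(pos, atoms_lab, natoms, box, pot, cutoff, N, frc);
  };

  refresh_orientation_caches();
  eval();

  // sampling containers
  int n_pos_frames = n_steps / pos_stride + 1;
  int n_vel_frames = n_steps / vel_stride + 1;
  int n_log = n_steps / log_stride + 1;
  NumericVector posF((R_xlen_t)3 * N * n_pos_frames);
  NumericVector velF((R_xlen_t)3 * N * n_vel_frames);
  NumericVector tposF(n_pos_frames), tvelF(n_vel_frames);
  NumericMatrix logm(n_log, 5);
  int ip = 0, iv = 0, il = 0;

  auto kinetic = [&](double& ket, double& ker) {
    ket = 0; ker = 0;
    for (int i = 0; i < N; ++i) {
      ket += 0.5 * mass * (vel[3 * i] * vel[3 * i] +
                           vel[3 * i + 1] * vel[3 * i + 1] +
                           vel[3 * i + 2] * vel[3 * i + 2]);
      ker += 0.5 * (I1 * om[3 * i] * om[3 * i] +
                    I2 * om[3 * i + 1] * om[3 * i + 1] +
                    I3 * om[3 * i + 2] * om[3 * i + 2]);
    }
  };

  auto sample = [&](int step) {
    double t = step * dt;
    if (step % pos_stride == 0 && ip < n_pos_frames) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k)
          posF[(R_xlen_t)3 * N * ip + (R_xlen_t)N * k + i] = pos[3 * i + k];
      tposF[ip] = t;
      ++ip;
    }
    if (step % vel_stride == 0 && iv < n_vel_frames) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k)
          velF[(R_xlen_t)3 * N * iv + (R_xlen_t)N * k + i] = vel[3 * i + k];
      tvelF[iv] = t;
      ++iv;
    }
    if (step % log_stride == 0 && il < n_log) {
      double ket, ker;
      kinetic(ket, ker);
      double tk = (ket + ker) / (3.0 * N * KB_INT);
      logm(il, 0) = t;
      logm(il, 1) = frc.pe;
      logm(il, 2) = ket / KCAL;
      logm(il, 3) = ker / KCAL;
      logm(il, 4) = tk;
      ++il;
    }
  };

  sample(0);

  double inv_m = 1.0 / mass;
  for (int step = 1; step <= n_steps; ++step) {
    // half kick (translation)
    for (int i = 0; i < 3 * N; ++i)
      vel[i] += 0.5 * dt * frc.F[i] * KCAL * inv_m;
    // half kick (rotation): body-frame Euler equations with torque
    for (int i = 0; i < N && I1 > 0; ++i) {
      double Q[3][3];
      quat_to_R(&quat[4 * i], Q);
      // body torque = Q^T tau_lab, converted to internal units
      double tb[3];
      for (int k = 0; k < 3; ++k)
        tb[k] = (Q[0][k] * frc.tau[3 * i] + Q[1][k] * frc.tau[3 * i + 1] +
                 Q[2][k] * frc.tau[3 * i + 2]) * KCAL;
      double* w = &om[3 * i];
      double w0[3] = {w[0], w[1], w[2]};
      for (int it = 0; it < 2; ++it) {
        double gy[3] = {
          (tb[0] - (I3 - I2) * w[1] * w[2]) / I1,
          (tb[1] - (I1 - I3) * w[2] * w[0]) / I2,
          (tb[2] - (I2 - I1) * w[0] * w[1]) / I3};
        for (int k = 0; k < 3; ++k) w[k] = w0[k] + 0.5 * dt * gy[k];
      }
    }
    // drift
    for (int i = 0; i < 3 * N; ++i) pos[i] += dt * vel[i];
    if (box > 0)
      for (int i = 0; i < 3 * N; ++i)
        pos[i] -= box * std::floor(pos[i] / box);
    // rotate quaternions by exp(dt * omega_body)
    for (int i = 0; i < N; ++i) {
      double* w = &om[3 * i];
      double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      double dq[4];
      if (wn < 1e-14) { dq[0] = 1; dq[1] = dq[2] = dq[3] = 0; }
      else {
        double half = 0.5 * wn * dt;
        double s = std::sin(half) / wn;
        dq[0] = std::cos(half);
        dq[1] = s * w[0]; dq[2] = s * w[1]; dq[3] = s * w[2];
      }
      double* q = &quat[4 * i];
      double nq[4] = {
        q[0] * dq[0] - q[1] * dq[1] - q[2] * dq[2] - q[3] * dq[3],
        q[0] * dq[1] + q[1] * dq[0] + q[2] * dq[3] - q[3] * dq[2],
        q[0] * dq[2] - q[1] * dq[3] + q[2] * dq[0] + q[3] * dq[1],
        q[0] * dq[3] + q[1] * dq[2] - q[2] * dq[1] + q[3] * dq[0]};
      double nn = std::sqrt(nq[0] * nq[0] + nq[1] * nq[1] + nq[2] * nq[2] +
                            nq[3] * nq[3]);
      for (int k = 0; k < 4; ++k) q[k] = nq[k] / nn;
    }
    // new forces
    refresh_orientation_caches();
    eval();
    // second half kick
    for (int i = 0; i < 3 * N; ++i)
      vel[i] += 0.5 * dt * frc.F[i] * KCAL * inv_m;
    for (int i = 0; i < N && I1 > 0; ++i) {
      double Q[3][3];
      quat_to_R(&quat[4 * i], Q);
      double tb[3];
      for (int k = 0; k < 3; ++k)
        tb[k] = (Q[0][k] * frc.tau[3 * i] + Q[1][k] * frc.tau[3 * i + 1] +
                 Q[2][k] * frc.tau[3 * i + 2]) * KCAL;
      double* w = &om[3 * i];
      double w0[3] = {w[0], w[1], w[2]};
      // implicit half kick: fixed-point iteration on the gyroscopic term
      for (int it = 0; it < 3; ++it) {
        double gy[3] = {
          (tb[0] - (I3 - I2) * w[1] * w[2]) / I1,
          (tb[1] - (I1 - I3) * w[2] * w[0]) / I2,
          (tb[2] - (I2 - I1) * w[0] * w[1]) / I3};
        for (int k = 0; k < 3; ++k) w[k] = w0[k] + 0.5 * dt * gy[k];
      }
    }
    // thermostat: translational and rotational subsystems rescaled
    // separately (a central CG potential exerts no torque, so a single
    // factor would let rotational KE drag the translational T off target)
    if (t_target > 0 && thermo_interval > 0 && step % thermo_interval == 0) {
      double ket, ker;
      kinetic(ket, ker);
      double tt = ket / (1.5 * N * KB_INT);
      double tr = ker / (1.5 * N * KB_INT);
      if (tt > 0) {
        double s = std::sqrt(t_target / tt);
        for (int i = 0; i < 3 * N; ++i) vel[i] *= s;
      }
      if (tr > 0) {
        double s = std::sqrt(t_target / tr);
        for (int i = 0; i < 3 * N; ++i) om[i] *= s;
      }
    }
    sample(step);
    if (step % 500 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < 3 * N; ++i)
      if (!std::isfinite(pos[i]))
        stop("integration failure: non-finite coordinate at step %d", step);
  }

  NumericMatrix posOut(N, 3), velOut(N, 3), quatOut(N, 4), omOut(N, 3);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) {
      posOut(i, k) = pos[3 * i + k];
      velOut(i, k) = vel[3 * i + k];
      omOut(i, k) = om[3 * i + k];
    }
    for (int k = 0; k < 4; ++k) quatOut(i, k) = quat[4 * i + k];
  }
  posF.attr("dim") = Dimension(N, 3, n_pos_frames);
  velF.attr("dim") = Dimension(N, 3, n_vel_frames);
  colnames(logm) = CharacterVector::create("time_ps", "pe_kcal",
                                           "ke_trans_kcal", "ke_rot_kcal",
                                           "T_kin");
  return List::create(
    _["positions"] = posF, _["times_pos"] = tposF,
    _["velocities"] = velF, _["times_vel"] = tvelF,
    _["log"] = logm,
    _["final_pos"] = posOut, _["final_vel"] = velOut,
    _["final_quat"] = quatOut, _["final_omega"] = omOut);
}

// ------------------------------------------------------- analysis helpers

// minimum-image pair-distance histogram over trajectory frames
// positions: N x 3 x F array; returns integer counts per bin of width dr
// over [0, r_max)
// [[Rcpp::export]]
NumericVector rdf_hist_cpp(NumericVector positions, double box, double dr,
                           double r_max) {
  IntegerVector dims = positions.attr("dim");
  int N = dims[0], F = dims[2];
  int nbins = (int)std::floor(r_max / dr + 0.5);
  NumericVector counts(nbins);
  const double* p = REAL(positions);
  for (int f = 0; f < F; ++f) {
    const double* fr = p + (R_xlen_t)3 * N * f;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double d[3] = {fr[i] - fr[j], fr[i + N] - fr[j + N],
                       fr[i + 2 * N] - fr[j + 2 * N]};
        min_image(d, box);
        double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (r < r_max) {
          int b = (int)(r / dr);
          if (b >= 0 && b < nbins) counts[b] += 1.0;
        }
      }
    }
  }
  return counts;
}
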