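#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time Collision
// Detection, ch. 5. Writes result into out[3], returns squared distance.
static double closestPointTriangle(const double *p, const double *a,
                                   const double *b, const double *c,
                                   double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = b[k];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) out[k] = c[k];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k)
                out[k] = a[k] + ab[k] * v + ac[k] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - out[0], dy = p[1] - out[1], dz = p[2] - out[2];
  return dx * dx + dy * dy + dz * dz;
}

// For each query point: closest point on the triangle mesh (V rows of 3,
// F rows of 1-based vertex index triples), accelerated by a uniform grid
// over face bounding boxes with expanding-shell search. Ties resolved by
// lowest face index (first minimum kept).
// [[Rcpp::export(name = ".meshClosestPoints")]]
List meshClosestPoints(NumericMatrix points, NumericMatrix V,
                       IntegerMatrix F) {
  int np = points.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector face(np);

  // bounding box of the mesh
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  int nv = V.nrow();
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      if (V(i, k) < lo[k]) lo[k] = V(i, k);
      if (V(i, k) > hi[k]) hi[k] = V(i, k);
    }
  double ext[3];
  double maxExt = 0.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = hi[k] - lo[k];
    if (ext[k] > maxExt) maxExt = ext[k];
  }
  // cell size: aim at O(1) faces per cell; degenerate extents fall back
  // to a single cell in that dimension
  double vol = 1.0;
  for (int k = 0; k < 3; ++k) vol *= std::max(ext[k], 1e-9 * maxExt + 1e-300);
  double h = std::cbrt(std::max(vol, 1e-300) / std::max(nf, 1));
  if (!(h > 0) || !R_FINITE(h)) h = 1.0;
  int dim[3];
  for (int k = 0; k < 3; ++k) {
    dim[k] = (int)std::floor(ext[k] / h) + 1;
    if (dim[k] < 1) dim[k] = 1;
    if (dim[k] > 128) dim[k] = 128;
  }
  double cell[3];
  for (int k = 0; k < 3; ++k)
    cell[k] = (ext[k] > 0) ? ext[k] / dim[k] : 1.0;

  // assign each face to all cells its bbox overlaps
  int ncell = dim[0] * dim[1] * dim[2];
  std::vector<std::vector<int> > bins(ncell);
  std::vector<double> va(3 * nf), vb(3 * nf), vc(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double flo[3], fhi[3];
    for (int k = 0; k < 3; ++k) {
      va[3 * f + k] = V(ia, k);
      vb[3 * f + k] = V(ib, k);
      vc[3 * f + k] = V(ic, k);
      flo[k] = std::min(V(ia, k), std::min(V(ib, k), V(ic, k)));
      fhi[k] = std::max(V(ia, k), std::max(V(ib, k), V(ic, k)));
    }
    int clo[3], chi[3];
    for (int k = 0; k < 3; ++k) {
      clo[k] = (int)((flo[k] - lo[k]) / cell[k]);
      chi[k] = (int)((fhi[k] - lo[k]) / cell[k]);
      if (clo[k] < 0) clo[k] = 0;
      if (chi[k] > dim[k] - 1) chi[k] = dim[k] - 1;
      if (clo[k] > dim[k] - 1) clo[k] = dim[k] - 1;
      if (chi[k] < 0) chi[k] = 0;
    }
    for (int x = clo[0]; x <= chi[0]; ++x)
      for (int y = clo[1]; y <= chi[1]; ++y)
        for (int z = clo[2]; z <= chi[2]; ++z)
          bins[(x * dim[1] + y) * dim[2] + z].push_back(f);
  }

  double minCell = std::min(cell[0], std::min(cell[1], cell[2]));
  std::vector<int> stamp(nf, -1);
  int maxRing = dim[0] + dim[1] + dim[2];

  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    int pc[3];
    for (int k = 0; k < 3; ++k) {
      pc[k] = (int)((p[k] - lo[k]) / cell[k]);
      if (pc[k] < 0) pc[k] = 0;
      if (pc[k] > dim[k] - 1) pc[k] = dim[k] - 1;
    }
    double best = R_PosInf, bestPt[3] = {0, 0, 0};
    int bestFace = -1;
    for (int ring = 0; ring <= maxRing; ++ring) {
      // all unexplored rings are at least (ring - 1) * minCell away from
      // the query point (conservative); stop once that exceeds best
      if (bestFace >= 0 && (double)(ring - 1) * minCell > std::sqrt(best))
        break;
      int xlo = std::max(pc[0] - ring, 0), xhi = std::min(pc[0] + ring, dim[0] - 1);
      int ylo = std::max(pc[1] - ring, 0), yhi = std::min(pc[1] + ring, dim[1] - 1);
      int zlo = std::max(pc[2] - ring, 0), zhi = std::min(pc[2] + ring, dim[2] - 1);
      for (int x = xlo; x <= xhi; ++x)
        for (int y = ylo; y <= yhi; ++y)
          for (int z = zlo; z <= zhi; ++z) {
            // only the shell surface (interior already visited)
            if (std::max(std::abs(x - pc[0]),
                         std::max(std::abs(y - pc[1]),
                                  std::abs(z - pc[2]))) != ring)
              continue;
            const std::vector<int> &bin = bins[(x * dim[1] + y) * dim[2] + z];
            for (size_t bi = 0; bi < bin.size(); ++bi) {
              int f = bin[bi];
              if (stamp[f] == i) continue;
              stamp[f] = i;
              double out[3];
              double d2 = closestPointTriangle(p, &va[3 * f], &vb[3 * f],
                                               &vc[3 * f], out);
              if (d2 < best || (d2 == best && f < bestFace)) {
                best = d2;
                bestFace = f;
                bestPt[0] = out[0];
                bestPt[1] = out[1];
                bestPt[2] = out[2];
              }
            }
          }
    }
    dist[i] = std::sqrt(best);
    face[i] = bestFace + 1;
    closest(i, 0) = bestPt[0];
    closest(i, 1) = bestPt[1];
    closest(i, 2) = bestPt[2];
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// Generalized winding number of each query point with respect to the mesh
// (van Oosterom & Strackee signed solid angle per triangle, summed, / 4pi).
// ~1 inside a closed outward-oriented surface, ~0 outside.
// [[Rcpp::export(name = ".meshWindingNumber")]]
NumericVector meshWindingNumber(NumericMatrix points, NumericMatrix V,
                                IntegerMatrix F) {
  int np = points.nrow(), nf = F.nrow();
  NumericVector w(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3], b[3], c[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = V(ia, k) - p[k];
        b[k] = V(ib, k) - p[k];
        c[k] = V(ic, k) - p[k];
      }
      double la = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
      double lb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
      double lc = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
      double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                   a[1] * (b[0] * c[2] - b[2] * c[0]) +
                   a[2] * (b[0] * c[1] - b[1] * c[0]);
      double dab = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
      double dbc = b[0] * c[0] + b[1] * c[1] + b[2] * c[2];
      double dca = c[0] * a[0] + c[1] * a[1] + c[2] * a[2];
      double denom = la * lb * lc + dab * lc + dbc * la + dca * lb;
      total += 2.0 * std::atan2(det, denom);
    }
    w[i] = total / (4.0 * M_PI);
  }
  return w;
}
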