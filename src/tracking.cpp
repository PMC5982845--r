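// Dense-video point tracking primitives.
//
// Frames are passed as a rows x cols x nframes array (frame-contiguous) of
// preprocessed gray levels. Coordinates are 0-based with x = column,
// y = row; the pixel (r, c) has its center at (x, y) = (c, r).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pyramid {
  // level 0 = full resolution; each level halves both dimensions
  std::vector<std::vector<double>> img;
  std::vector<int> nr, nc;
};

// bilinear sample with clamped borders; (x, y) in 0-based pixel coords
inline double sample(const std::vector<double> &m, int nr, int nc, double x,
                     double y) {
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (x > nc - 1) x = nc - 1;
  if (y > nr - 1) y = nr - 1;
  int c0 = (int)std::floor(x), r0 = (int)std::floor(y);
  int c1 = std::min(c0 + 1, nc - 1), r1 = std::min(r0 + 1, nr - 1);
  double ax = x - c0, ay = y - r0;
  double v00 = m[(size_t)r0 + (size_t)c0 * nr];
  double v01 = m[(size_t)r0 + (size_t)c1 * nr];
  double v10 = m[(size_t)r1 + (size_t)c0 * nr];
  double v11 = m[(size_t)r1 + (size_t)c1 * nr];
  return (1 - ay) * ((1 - ax) * v00 + ax * v01) +
         ay * ((1 - ax) * v10 + ax * v11);
}

Pyramid build_pyramid(const double *frame, int nr, int nc, int levels) {
  Pyramid p;
  p.img.resize(levels);
  p.nr.resize(levels);
  p.nc.resize(levels);
  p.img[0].assign(frame, frame + (size_t)nr * nc);
  p.nr[0] = nr;
  p.nc[0] = nc;
  for (int l = 1; l < levels; ++l) {
    int pr = p.nr[l - 1], pc = p.nc[l - 1];
    int cr = pr / 2, cc = pc / 2;
    p.nr[l] = cr;
    p.nc[l] = cc;
    p.img[l].assign((size_t)cr * cc, 0.0);
    for (int c = 0; c < cc; ++c)
      for (int r = 0; r < cr; ++r) {
        const std::vector<double> &up = p.img[l - 1];
        double s = up[(size_t)(2 * r) + (size_t)(2 * c) * pr] +
                   up[(size_t)(2 * r + 1) + (size_t)(2 * c) * pr] +
                   up[(size_t)(2 * r) + (size_t)(2 * c + 1) * pr] +
                   up[(size_t)(2 * r + 1) + (size_t)(2 * c + 1) * pr];
        p.img[l][(size_t)r + (size_t)c * cr] = 0.25 * s;
      }
  }
  return p;
}

}  // namespace

// Pyramidal Lucas-Kanade tracking of seed points across a frame stack.
// frames: rows x cols x nframes numeric array; seeds: n x 2 matrix (x, y).
// Returns positions (n x nframes x 2) and validity (n x nframes).
// A point turns (and stays) invalid when its patch leaves the frame, the
// normal equations become singular, a frame-to-frame step diverges, or the
// final residual is too large.
// [[Rcpp::export(name = ".klt_track_cpp")]]
List klt_track_cpp(NumericVector frames, NumericMatrix seeds,
                   int pyramid_levels = 3, int patch = 21, int max_iter = 30,
                   double eps = 0.01, double max_step = 8.0,
                   double max_residual = 0.5) {
  IntegerVector dims = frames.attr("dim");
  int nr = dims[0], nc = dims[1], nf = dims[2];
  int np = seeds.nrow();
  int hw = patch / 2;

  // cap pyramid so the coarsest level still holds a patch
  int levels = pyramid_levels;
  while (levels > 1 &&
         ((nr >> (levels - 1)) < patch + 2 || (nc >> (levels - 1)) < patch + 2))
    --levels;

  NumericVector positions(Dimension(np, nf, 2));
  LogicalMatrix valid(np, nf);
  std::vector<double> px(np), py(np);
  std::vector<bool> alive(np, true);
  for (int i = 0; i < np; ++i) {
    px[i] = seeds(i, 0);
    py[i] = seeds(i, 1);
    positions[i] = px[i];
    positions[i + (size_t)np * nf] = py[i];
    bool in = px[i] >= hw + 1 && px[i] <= nc - hw - 2 && py[i] >= hw + 1 &&
              py[i] <= nr - hw - 2;
    alive[i] = in;
    valid(i, 0) = in;
  }

  const double *base = REAL(frames);
  Pyramid prev = build_pyramid(base, nr, nc, levels);

  std::vector<double> tmpl((size_t)patch * patch), gx((size_t)patch * patch),
      gy((size_t)patch * patch);

  for (int f = 1; f < nf; ++f) {
    Pyramid cur = build_pyramid(base + (size_t)f * nr * nc, nr, nc, levels);
    for (int i = 0; i < np; ++i) {
      if (!alive[i]) {
        positions[i + (size_t)np * f] = px[i];
        positions[i + (size_t)np * f + (size_t)np * nf] = py[i];
        continue;
      }
      double gx0 = 0.0, gy0 = 0.0;  // displacement guess carried across levels
      bool ok = true;
      double resid = 0.0;
      for (int l = levels - 1; l >= 0 && ok; --l) {
        double s = 1.0 / (1 << l);
        double tx = px[i] * s, ty = py[i] * s;  // template center, prev frame
        int lnr = prev.nr[l], lnc = prev.nc[l];
        if (tx < hw + 1 || tx > lnc - hw - 2 || ty < hw + 1 ||
            ty > lnr - hw - 2) {
          if (l == 0) ok = false;
          continue;  // skip too-coarse level for border points
        }
        // sample the template patch and its gradients once per level
        for (int cpt = -hw; cpt <= hw; ++cpt)
          for (int rpt = -hw; rpt <= hw; ++rpt) {
            size_t k = (size_t)(rpt + hw) + (size_t)(cpt + hw) * patch;
            double xx = tx + cpt, yy = ty + rpt;
            tmpl[k] = sample(prev.img[l], lnr, lnc, xx, yy);
            gx[k] = 0.5 * (sample(prev.img[l], lnr, lnc, xx + 1, yy) -
                           sample(prev.img[l], lnr, lnc, xx - 1, yy));
            gy[k] = 0.5 * (sample(prev.img[l], lnr, lnc, xx, yy + 1) -
                           sample(prev.img[l], lnr, lnc, xx, yy - 1));
          }
        double tmean = 0, tss = 0;
        for (size_t k = 0; k < (size_t)patch * patch; ++k) tmean += tmpl[k];
        tmean /= (double)patch * patch;
        for (size_t k = 0; k < (size_t)patch * patch; ++k)
          tss += (tmpl[k] - tmean) * (tmpl[k] - tmean);
        double dx = gx0, dy = gy0;
        // Symmetric (ESM-style) Gauss-Newton: gradients are the average of
        // the template gradient and the current-image gradient at the
        // present estimate, which cancels the first-order interpolation
        // bias of one-sided Lucas-Kanade and keeps sub-pixel gain near 1.
        // The residual is affine-intensity-compensated (zero-meaned and
        // contrast-equalized) so per-frame contrast renormalization of the
        // preprocessed video cannot bias the motion estimate.
        for (int it = 0; it < max_iter; ++it) {
          double imean = 0, iss = 0;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt)
              imean += sample(cur.img[l], lnr, lnc, tx + dx + cpt,
                              ty + dy + rpt);
          imean /= (double)patch * patch;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt) {
              double v = sample(cur.img[l], lnr, lnc, tx + dx + cpt,
                                ty + dy + rpt) -
                         imean;
              iss += v * v;
            }
          double gain = (iss > 1e-12) ? std::sqrt(tss / iss) : 1.0;
          double Gxx = 0, Gxy = 0, Gyy = 0, bx = 0, by = 0;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt) {
              size_t k = (size_t)(rpt + hw) + (size_t)(cpt + hw) * patch;
              double xx = tx + dx + cpt, yy = ty + dy + rpt;
              double igx =
                  gain * 0.5 * (sample(cur.img[l], lnr, lnc, xx + 1, yy) -
                                sample(cur.img[l], lnr, lnc, xx - 1, yy));
              double igy =
                  gain * 0.5 * (sample(cur.img[l], lnr, lnc, xx, yy + 1) -
                                sample(cur.img[l], lnr, lnc, xx, yy - 1));
              double mgx = 0.5 * (gx[k] + igx);
              double mgy = 0.5 * (gy[k] + igy);
              double diff =
                  gain * (sample(cur.img[l], lnr, lnc, xx, yy) - imean) -
                  (tmpl[k] - tmean);
              Gxx += mgx * mgx;
              Gxy += mgx * mgy;
              Gyy += mgy * mgy;
              bx += diff * mgx;
              by += diff * mgy;
            }
          double det = Gxx * Gyy - Gxy * Gxy;
          if (det < 1e-12) {
            ok = false;
            break;
          }
          double ux = (Gyy * bx - Gxy * by) / det;
          double uy = (Gxx * by - Gxy * bx) / det;
          dx -= ux;
          dy -= uy;
          if (std::sqrt(ux * ux + uy * uy) < eps) break;
          if (std::sqrt(dx * dx + dy * dy) > max_step) {
            ok = false;
            break;
          }
        }
        if (!ok) break;
        if (l > 0) {
          gx0 = 2.0 * dx;
          gy0 = 2.0 * dy;
        } else {
          // final affine-compensated residual at full resolution
          double imean = 0, iss = 0;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt)
              imean += sample(cur.img[0], nr, nc, tx + dx + cpt,
                              ty + dy + rpt);
          imean /= (double)patch * patch;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt) {
              double v = sample(cur.img[0], nr, nc, tx + dx + cpt,
                                ty + dy + rpt) -
                         imean;
              iss += v * v;
            }
          double gain = (iss > 1e-12) ? std::sqrt(tss / iss) : 1.0;
          double sum = 0;
          for (int cpt = -hw; cpt <= hw; ++cpt)
            for (int rpt = -hw; rpt <= hw; ++rpt) {
              size_t k = (size_t)(rpt + hw) + (size_t)(cpt + hw) * patch;
              sum += std::fabs(gain * (sample(cur.img[0], nr, nc,
                                              tx + dx + cpt, ty + dy + rpt) -
                                       imean) -
                               (tmpl[k] - tmean));
            }
          resid = sum / ((double)patch * patch);
          gx0 = dx;
          gy0 = dy;
        }
      }
      double nx = px[i] + gx0, ny = py[i] + gy0;
      if (ok && (nx < hw + 1 || nx > nc - hw - 2 || ny < hw + 1 ||
                 ny > nr - hw - 2))
        ok = false;  // exited the frame
      if (ok && resid > max_residual) ok = false;
      if (ok) {
        px[i] = nx;
        py[i] = ny;
        valid(i, f) = true;
      } else {
        alive[i] = false;
      }
      positions[i + (size_t)np * f] = px[i];
      positions[i + (size_t)np * f + (size_t)np * nf] = py[i];
    }
    prev = std::move(cur);
  }
  return List::create(_["positions"] = positions, _["valid"] = valid);
}

// Integer-pixel template tracking by normalized cross-correlation.
// frames: rows x cols x nframes; the template is the given rectangle of
// frame 1, searched within +-radius of the previous offset in every later
// frame. Returns per-frame (drow, dcol) offsets and the peak correlation.
// [[Rcpp::export(name = ".ncc_track_cpp")]]
List ncc_track_cpp(NumericVector frames, int row0, int col0, int height,
                   int width, int radius = 20) {
  IntegerVector dims = frames.attr("dim");
  int nr = dims[0], nc = dims[1], nf = dims[2];
  const double *base = REAL(frames);

  std::vector<double> tmpl((size_t)height * width);
  double tmean = 0;
  for (int c = 0; c < width; ++c)
    for (int r = 0; r < height; ++r) {
      double v = base[(size_t)(row0 + r) + (size_t)(col0 + c) * nr];
      tmpl[(size_t)r + (size_t)c * height] = v;
      tmean += v;
    }
  tmean /= (double)height * width;
  double tss = 0;
  for (double &v : tmpl) {
    v -= tmean;
    tss += v * v;
  }
  IntegerMatrix offsets(nf, 2);
  NumericVector peak(nf);
  peak[0] = 1.0;
  if (tss <= 1e-12)
    return List::create(_["offsets"] = offsets, _["peak"] = peak,
                        _["flat_template"] = true);

  int pr = 0, pc = 0;  // previous offset
  for (int f = 1; f < nf; ++f) {
    const double *img = base + (size_t)f * nr * nc;
    double best = -2.0;
    int br = pr, bc = pc;
    for (int dr = pr - radius; dr <= pr + radius; ++dr) {
      if (row0 + dr < 0 || row0 + dr + height > nr) continue;
      for (int dc = pc - radius; dc <= pc + radius; ++dc) {
        if (col0 + dc < 0 || col0 + dc + width > nc) continue;
        double s = 0, ss = 0, cross = 0;
        for (int c = 0; c < width; ++c)
          for (int r = 0; r < height; ++r) {
            double v = img[(size_t)(row0 + dr + r) + (size_t)(col0 + dc + c) * nr];
            s += v;
            ss += v * v;
            cross += v * tmpl[(size_t)r + (size_t)c * height];
          }
        double n = (double)height * width;
        double var = ss - s * s / n;
        if (var <= 1e-12) continue;
        double corr = cross / std::sqrt(var * tss);
        if (corr > best) {
          best = corr;
          br = dr;
          bc = dc;
        }
      }
    }
    offsets(f, 0) = br;
    offsets(f, 1) = bc;
    peak[f] = best;
    pr = br;
    pc = bc;
  }
  return List::create(_["offsets"] = offsets, _["peak"] = peak,
                      _["flat_template"] = false);
}
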