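// Steady incompressible Navier-Stokes in conservation form, discretized
// with a colocated cell-centered finite-volume method.
//
// The tetrahedral mesh is the geometric substrate; control volumes are
// formed by agglomerating user-specified groups of tetrahedra (the swept
// mesher groups the 3 tetrahedra of each thin prism, which restores face
// orthogonality in the graded inflation layers; pass the identity map to
// solve on raw tetrahedra). Faces stay triangulated; fluxes are summed
// per triangle, so the scheme remains conservative.
//
// Numerics: first-order upwind convection, central diffusion with
// over-relaxed non-orthogonality correction, Green-Gauss gradients,
// SIMPLE pressure-velocity coupling with Rhie-Chow face interpolation.
// Boundaries: no-slip walls; fixed-pressure inlet/outlet with
// zero-gradient velocity (inflowing momentum is taken from the face-normal
// velocity implied by the mass flux, which keeps the inlet stable).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TripleHash {
  std::size_t operator()(const std::array<int, 3>& k) const {
    std::size_t h = 1469598103934665603ULL;
    for (int v : k) {
      h ^= static_cast<std::size_t>(v);
      h *= 1099511628211ULL;
    }
    return h;
  }
};

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

} // namespace

// [[Rcpp::export(name = ".fvm_simple_cpp")]]
List fvm_simple_cpp(NumericMatrix verts, IntegerMatrix tets,
                    IntegerVector cell_of_tet,
                    IntegerMatrix bfaces, IntegerVector blabel,
                    double rho, double mu,
                    double p_inlet, double p_outlet,
                    double relax_u, double relax_p,
                    int max_outer, double tol, int n_sweeps,
                    NumericMatrix u_init, NumericVector p_init,
                    bool verbose) {
  const int nv = verts.nrow();
  const int nt = tets.nrow();
  const int nb = bfaces.nrow();
  if (cell_of_tet.size() != nt) stop("cell_of_tet must map every tetrahedron");

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }

  int nc = 0;
  std::vector<int> cmap(nt);
  for (int t = 0; t < nt; ++t) {
    cmap[t] = cell_of_tet[t] - 1;
    if (cmap[t] < 0) stop("cell ids must be positive");
    nc = std::max(nc, cmap[t] + 1);
  }

  // control-volume centroids and volumes (volume-weighted over member tets)
  std::vector<double> ccx(nc, 0.0), ccy(nc, 0.0), ccz(nc, 0.0), vol(nc, 0.0);
  for (int t = 0; t < nt; ++t) {
    int a = tets(t, 0) - 1, b = tets(t, 1) - 1,
        d = tets(t, 2) - 1, e = tets(t, 3) - 1;
    double b1[3] = { vx[b] - vx[a], vy[b] - vy[a], vz[b] - vz[a] };
    double b2[3] = { vx[d] - vx[a], vy[d] - vy[a], vz[d] - vz[a] };
    double b3[3] = { vx[e] - vx[a], vy[e] - vy[a], vz[e] - vz[a] };
    double det = b1[0] * (b2[1] * b3[2] - b2[2] * b3[1])
               - b1[1] * (b2[0] * b3[2] - b2[2] * b3[0])
               + b1[2] * (b2[0] * b3[1] - b2[1] * b3[0]);
    double vt = det / 6.0;
    if (vt <= 0.0) stop("negatively oriented tetrahedron %d", t + 1);
    int c = cmap[t];
    double cx = 0.25 * (vx[a] + vx[b] + vx[d] + vx[e]);
    double cy = 0.25 * (vy[a] + vy[b] + vy[d] + vy[e]);
    double cz = 0.25 * (vz[a] + vz[b] + vz[d] + vz[e]);
    ccx[c] += vt * cx; ccy[c] += vt * cy; ccz[c] += vt * cz;
    vol[c] += vt;
  }
  for (int c = 0; c < nc; ++c) {
    if (vol[c] <= 0.0) stop("empty control volume %d", c + 1);
    ccx[c] /= vol[c]; ccy[c] /= vol[c]; ccz[c] /= vol[c];
  }

  // triangular faces between distinct control volumes, via hashing
  struct Face { int v0, v1, v2, owner, neigh, label; };
  std::vector<Face> faces;
  faces.reserve(2 * nt + nb);
  std::unordered_map<std::array<int, 3>, int, TripleHash> fmap;
  fmap.reserve(4 * nt);
  const int fv[4][3] = { {0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3} };
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < 4; ++k) {
      std::array<int, 3> key = { tets(t, fv[k][0]) - 1,
                                 tets(t, fv[k][1]) - 1,
                                 tets(t, fv[k][2]) - 1 };
      std::sort(key.begin(), key.end());
      auto it = fmap.find(key);
      if (it == fmap.end()) {
        Face f; f.v0 = key[0]; f.v1 = key[1]; f.v2 = key[2];
        f.owner = cmap[t]; f.neigh = -1; f.label = 0;
        fmap.emplace(key, static_cast<int>(faces.size()));
        faces.push_back(f);
      } else {
        faces[it->second].neigh = cmap[t];
      }
    }
  }
  // attach boundary labels (1 wall, 2 inlet, 3 outlet)
  for (int i = 0; i < nb; ++i) {
    std::array<int, 3> key = { bfaces(i, 0) - 1, bfaces(i, 1) - 1,
                               bfaces(i, 2) - 1 };
    std::sort(key.begin(), key.end());
    auto it = fmap.find(key);
    if (it == fmap.end()) stop("boundary face %d not found in the mesh", i + 1);
    if (faces[it->second].neigh != -1)
      stop("boundary face %d is interior", i + 1);
    faces[it->second].label = blabel[i];
  }
  {
    // drop faces internal to a control volume; keep boundary + inter-cell
    std::vector<Face> kept;
    kept.reserve(faces.size());
    for (const Face& f : faces) {
      if (f.neigh == -1) {
        if (f.label == 0) stop("unlabeled boundary face in the mesh");
        kept.push_back(f);
      } else if (f.neigh != f.owner) {
        kept.push_back(f);
      }
    }
    faces.swap(kept);
  }
  const int nf = static_cast<int>(faces.size());

  // face geometry
  std::vector<double> sfx(nf), sfy(nf), sfz(nf), smag(nf);
  std::vector<double> dx(nf), dy(nf), dz(nf), alphaf(nf), gw(nf);
  for (int f = 0; f < nf; ++f) {
    const Face& F = faces[f];
    double e1[3] = { vx[F.v1] - vx[F.v0], vy[F.v1] - vy[F.v0], vz[F.v1] - vz[F.v0] };
    double e2[3] = { vx[F.v2] - vx[F.v0], vy[F.v2] - vy[F.v0], vz[F.v2] - vz[F.v0] };
    double n[3] = { 0.5 * (e1[1] * e2[2] - e1[2] * e2[1]),
                    0.5 * (e1[2] * e2[0] - e1[0] * e2[2]),
                    0.5 * (e1[0] * e2[1] - e1[1] * e2[0]) };
    double fcx = (vx[F.v0] + vx[F.v1] + vx[F.v2]) / 3.0;
    double fcy = (vy[F.v0] + vy[F.v1] + vy[F.v2]) / 3.0;
    double fcz = (vz[F.v0] + vz[F.v1] + vz[F.v2]) / 3.0;
    double to_f[3] = { fcx - ccx[F.owner], fcy - ccy[F.owner],
                       fcz - ccz[F.owner] };
    if (dot3(n, to_f) < 0) { n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2]; }
    sfx[f] = n[0]; sfy[f] = n[1]; sfz[f] = n[2];
    smag[f] = std::sqrt(dot3(n, n));
    if (F.neigh >= 0) {
      dx[f] = ccx[F.neigh] - ccx[F.owner];
      dy[f] = ccy[F.neigh] - ccy[F.owner];
      dz[f] = ccz[F.neigh] - ccz[F.owner];
      double dfP = std::sqrt((fcx - ccx[F.owner]) * (fcx - ccx[F.owner]) +
                             (fcy - ccy[F.owner]) * (fcy - ccy[F.owner]) +
                             (fcz - ccz[F.owner]) * (fcz - ccz[F.owner]));
      double dfN = std::sqrt((fcx - ccx[F.neigh]) * (fcx - ccx[F.neigh]) +
                             (fcy - ccy[F.neigh]) * (fcy - ccy[F.neigh]) +
                             (fcz - ccz[F.neigh]) * (fcz - ccz[F.neigh]));
      gw[f] = dfN / (dfP + dfN);   // weight of the owner value
    } else {
      dx[f] = fcx - ccx[F.owner];
      dy[f] = fcy - ccy[F.owner];
      dz[f] = fcz - ccz[F.owner];
      gw[f] = 1.0;
    }
    double dvec[3] = { dx[f], dy[f], dz[f] };
    double sn[3] = { sfx[f], sfy[f], sfz[f] };
    double sd = dot3(sn, dvec);
    if (sd <= 0) stop("non-positive face orthogonality metric (face %d)", f + 1);
    alphaf[f] = smag[f] * smag[f] / sd;   // over-relaxed decomposition
  }

  // fields
  std::vector<double> u(nc, 0.0), v(nc, 0.0), w(nc, 0.0), p(nc, 0.0);
  if (u_init.nrow() == nc) {
    for (int c = 0; c < nc; ++c) {
      u[c] = u_init(c, 0); v[c] = u_init(c, 1); w[c] = u_init(c, 2);
    }
  }
  if (p_init.size() == nc) {
    for (int c = 0; c < nc; ++c) p[c] = p_init[c];
  } else {
    for (int c = 0; c < nc; ++c) p[c] = p_inlet;
  }

  std::vector<double> mdot(nf, 0.0);
  std::vector<double> gpx(nc), gpy(nc), gpz(nc);
  std::vector<double> gux(nc), guy(nc), guz(nc);  // reused per component
  std::vector<double> aP(nc), bsrc(nc);
  std::vector<double> aF(nf);                      // symmetric off-diagonal part
  std::vector<double> convP(nf), convN(nf);
  std::vector<double> Dcell(nc, 0.0);
  std::vector<double> pc(nc), pcr(nc), pcz_(nc), pcp(nc), pcAp(nc), diagp(nc);

  auto green_gauss = [&](const std::vector<double>& phi,
                         std::vector<double>& gx, std::vector<double>& gy,
                         std::vector<double>& gz,
                         int bc_mode, double bin, double bout) {
    // bc_mode 0: velocity (wall = 0, in/out zero-gradient)
    // bc_mode 1: pressure (wall zero-gradient, in/out fixed bin/bout)
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    for (int f = 0; f < nf; ++f) {
      const Face& F = faces[f];
      double phif;
      if (F.neigh >= 0) {
        phif = gw[f] * phi[F.owner] + (1.0 - gw[f]) * phi[F.neigh];
      } else if (bc_mode == 0) {
        phif = (F.label == 1) ? 0.0 : phi[F.owner];
      } else {
        phif = (F.label == 1) ? phi[F.owner]
             : (F.label == 2) ? bin : bout;
      }
      gx[F.owner] += phif * sfx[f];
      gy[F.owner] += phif * sfy[f];
      gz[F.owner] += phif * sfz[f];
      if (F.neigh >= 0) {
        gx[F.neigh] -= phif * sfx[f];
        gy[F.neigh] -= phif * sfy[f];
        gz[F.neigh] -= phif * sfz[f];
      }
    }
    for (int c = 0; c < nc; ++c) {
      gx[c] /= vol[c]; gy[c] /= vol[c]; gz[c] /= vol[c];
    }
  };

  // cell -> faces adjacency for Gauss-Seidel
  std::vector<int> cf_start(nc + 1, 0);
  for (int f = 0; f < nf; ++f) {
    cf_start[faces[f].owner + 1]++;
    if (faces[f].neigh >= 0) cf_start[faces[f].neigh + 1]++;
  }
  for (int c = 0; c < nc; ++c) cf_start[c + 1] += cf_start[c];
  std::vector<int> cf_face(cf_start[nc]), cf_other(cf_start[nc]);
  {
    std::vector<int> pos(cf_start.begin(), cf_start.end() - 1);
    for (int f = 0; f < nf; ++f) {
      int P = faces[f].owner, N = faces[f].neigh;
      cf_face[pos[P]] = f; cf_other[pos[P]++] = N;
      if (N >= 0) { cf_face[pos[N]] = f; cf_other[pos[N]++] = P; }
    }
  }

  const double small = 1e-300;
  NumericMatrix res_hist(max_outer, 4);
  int it_done = 0;
  bool converged = false;
  double res_u = 1, res_v = 1, res_w = 1, res_c = 1;

  for (int outer = 0; outer < max_outer; ++outer) {
    green_gauss(p, gpx, gpy, gpz, 1, p_inlet, p_outlet);

    double res_mom[3] = {0, 0, 0};
    double ref_mom = 0.0;

    // --- momentum: assemble and solve each component --------------------
    std::vector<double>* comp[3] = { &u, &v, &w };
    double* gp[3] = { gpx.data(), gpy.data(), gpz.data() };
    for (int cdir = 0; cdir < 3; ++cdir) {
      std::vector<double>& phi = *comp[cdir];
      green_gauss(phi, gux, guy, guz, 0, 0, 0);
      std::fill(aP.begin(), aP.end(), 0.0);
      std::fill(bsrc.begin(), bsrc.end(), 0.0);
      for (int f = 0; f < nf; ++f) {
        const Face& F = faces[f];
        if (F.neigh >= 0) {
          double diff = mu * alphaf[f];
          double m = mdot[f];
          aP[F.owner] += diff + std::max(m, 0.0);
          aP[F.neigh] += diff + std::max(-m, 0.0);
          aF[f] = -diff;             // symmetric part; convection below
          convP[f] = std::max(m, 0.0);
          convN[f] = std::max(-m, 0.0);
          // non-orthogonal diffusion correction (deferred)
          double gfx = gw[f] * gux[F.owner] + (1 - gw[f]) * gux[F.neigh];
          double gfy = gw[f] * guy[F.owner] + (1 - gw[f]) * guy[F.neigh];
          double gfz = gw[f] * guz[F.owner] + (1 - gw[f]) * guz[F.neigh];
          double tx = sfx[f] - alphaf[f] * dx[f];
          double ty = sfy[f] - alphaf[f] * dy[f];
          double tz = sfz[f] - alphaf[f] * dz[f];
          double corr = mu * (gfx * tx + gfy * ty + gfz * tz);
          bsrc[F.owner] += corr;
          bsrc[F.neigh] -= corr;
        } else if (F.label == 1) {   // wall, no-slip
          aP[F.owner] += mu * alphaf[f];
          aF[f] = 0; convP[f] = 0; convN[f] = 0;
        } else {                     // pressure boundary
          double m = mdot[f];
          if (m > 0) {
            aP[F.owner] += m;        // outflow: upwind cell value, implicit
          } else {
            // inflow: convect the face-normal velocity implied by the
            // mass flux itself (no feedback through the cell velocity)
            double sc = (cdir == 0) ? sfx[f] : (cdir == 1) ? sfy[f] : sfz[f];
            double uin = m * sc / (rho * smag[f] * smag[f]);
            bsrc[F.owner] -= m * uin;
          }
          aF[f] = 0; convP[f] = 0; convN[f] = 0;
        }
      }
      for (int c = 0; c < nc; ++c)
        bsrc[c] -= gp[cdir][c] * vol[c];

      // under-relaxation
      for (int c = 0; c < nc; ++c) {
        double a0 = aP[c];
        aP[c] = a0 / relax_u;
        bsrc[c] += (1.0 - relax_u) / relax_u * a0 * phi[c];
      }
      if (cdir == 0)
        for (int c = 0; c < nc; ++c) Dcell[c] = vol[c] / aP[c];

      // scaled residual of the current iterate
      double rsum = 0.0, rref = 0.0;
      for (int c = 0; c < nc; ++c) {
        double ax = aP[c] * phi[c];
        for (int k = cf_start[c]; k < cf_start[c + 1]; ++k) {
          int f = cf_face[k], o = cf_other[k];
          if (o < 0) continue;
          bool is_owner = (faces[f].owner == c);
          double coef = aF[f] - (is_owner ? convN[f] : convP[f]);
          ax += coef * phi[o];
        }
        rsum += std::fabs(bsrc[c] - ax);
        rref += std::fabs(aP[c] * phi[c]) + std::fabs(bsrc[c]);
      }
      ref_mom = std::max(ref_mom, rref);
      res_mom[cdir] = rsum;

      // Gauss-Seidel sweeps (forward + backward)
      for (int sweep = 0; sweep < n_sweeps; ++sweep) {
        for (int c = 0; c < nc; ++c) {
          double s = bsrc[c];
          for (int k = cf_start[c]; k < cf_start[c + 1]; ++k) {
            int f = cf_face[k], o = cf_other[k];
            if (o < 0) continue;
            bool is_owner = (faces[f].owner == c);
            double coef = aF[f] - (is_owner ? convN[f] : convP[f]);
            s -= coef * phi[o];
          }
          phi[c] = s / aP[c];
        }
        for (int c = nc - 1; c >= 0; --c) {
          double s = bsrc[c];
          for (int k = cf_start[c]; k < cf_start[c + 1]; ++k) {
            int f = cf_face[k], o = cf_other[k];
            if (o < 0) continue;
            bool is_owner = (faces[f].owner == c);
            double coef = aF[f] - (is_owner ? convN[f] : convP[f]);
            s -= coef * phi[o];
          }
          phi[c] = s / aP[c];
        }
      }
    }

    // --- Rhie-Chow face mass fluxes -------------------------------------
    green_gauss(p, gpx, gpy, gpz, 1, p_inlet, p_outlet);
    for (int f = 0; f < nf; ++f) {
      const Face& F = faces[f];
      if (F.neigh >= 0) {
        double g = gw[f];
        double uf = g * u[F.owner] + (1 - g) * u[F.neigh];
        double vf = g * v[F.owner] + (1 - g) * v[F.neigh];
        double wf = g * w[F.owner] + (1 - g) * w[F.neigh];
        double Df = g * Dcell[F.owner] + (1 - g) * Dcell[F.neigh];
        double gfx = g * gpx[F.owner] + (1 - g) * gpx[F.neigh];
        double gfy = g * gpy[F.owner] + (1 - g) * gpy[F.neigh];
        double gfz = g * gpz[F.owner] + (1 - g) * gpz[F.neigh];
        double dp = p[F.neigh] - p[F.owner];
        double gdotd = gfx * dx[f] + gfy * dy[f] + gfz * dz[f];
        mdot[f] = rho * (uf * sfx[f] + vf * sfy[f] + wf * sfz[f]
                         - Df * alphaf[f] * (dp - gdotd));
      } else if (F.label == 1) {
        mdot[f] = 0.0;
      } else {
        double pb = (F.label == 2) ? p_inlet : p_outlet;
        double dp = pb - p[F.owner];
        double gdotd = gpx[F.owner] * dx[f] + gpy[F.owner] * dy[f]
                     + gpz[F.owner] * dz[f];
        mdot[f] = rho * (u[F.owner] * sfx[f] + v[F.owner] * sfy[f]
                         + w[F.owner] * sfz[f]
                         - Dcell[F.owner] * alphaf[f] * (dp - gdotd));
      }
    }

    // --- pressure correction --------------------------------------------
    std::fill(diagp.begin(), diagp.end(), 0.0);
    std::fill(pcr.begin(), pcr.end(), 0.0);
    for (int f = 0; f < nf; ++f) {
      const Face& F = faces[f];
      if (F.neigh >= 0) {
        double g = gw[f];
        double Df = g * Dcell[F.owner] + (1 - g) * Dcell[F.neigh];
        double cfc = rho * Df * alphaf[f];
        aF[f] = cfc;
        diagp[F.owner] += cfc;
        diagp[F.neigh] += cfc;
        pcr[F.owner] -= mdot[f];
        pcr[F.neigh] += mdot[f];
      } else {
        if (F.label != 1) {
          double cfc = rho * Dcell[F.owner] * alphaf[f];
          aF[f] = cfc;
          diagp[F.owner] += cfc;
        } else aF[f] = 0.0;
        pcr[F.owner] -= mdot[f];
      }
    }
    // mass-imbalance residual (before correction)
    double mass_res = 0.0;
    for (int c = 0; c < nc; ++c) mass_res += std::fabs(pcr[c]);

    // CG with Jacobi preconditioning on the p' system
    std::fill(pc.begin(), pc.end(), 0.0);
    {
      // a loose inner solve is enough: SIMPLE re-assembles every outer pass
      double r0 = 0.0;
      for (int c = 0; c < nc; ++c) r0 += pcr[c] * pcr[c];
      double tol2 = std::max(r0 * 2.5e-3, 1e-300);
      for (int c = 0; c < nc; ++c) pcz_[c] = pcr[c] / (diagp[c] + small);
      std::copy(pcz_.begin(), pcz_.end(), pcp.begin());
      double rz = 0.0;
      for (int c = 0; c < nc; ++c) rz += pcr[c] * pcz_[c];
      int cg_max = 250;
      for (int cg = 0; cg < cg_max; ++cg) {
        for (int c = 0; c < nc; ++c) pcAp[c] = diagp[c] * pcp[c];
        for (int f = 0; f < nf; ++f) {
          const Face& F = faces[f];
          if (F.neigh < 0) continue;
          pcAp[F.owner] -= aF[f] * pcp[F.neigh];
          pcAp[F.neigh] -= aF[f] * pcp[F.owner];
        }
        double pAp = 0.0;
        for (int c = 0; c < nc; ++c) pAp += pcp[c] * pcAp[c];
        if (pAp <= 0) break;
        double alpha = rz / pAp;
        double rnew2 = 0.0;
        for (int c = 0; c < nc; ++c) {
          pc[c] += alpha * pcp[c];
          pcr[c] -= alpha * pcAp[c];
          rnew2 += pcr[c] * pcr[c];
        }
        if (rnew2 < tol2) break;
        double rznew = 0.0;
        for (int c = 0; c < nc; ++c) {
          pcz_[c] = pcr[c] / (diagp[c] + small);
          rznew += pcr[c] * pcz_[c];
        }
        double beta = rznew / rz;
        rz = rznew;
        for (int c = 0; c < nc; ++c) pcp[c] = pcz_[c] + beta * pcp[c];
      }
    }

    // corrections
    for (int c = 0; c < nc; ++c) p[c] += relax_p * pc[c];
    for (int f = 0; f < nf; ++f) {
      const Face& F = faces[f];
      if (F.neigh >= 0)
        mdot[f] += aF[f] * (pc[F.owner] - pc[F.neigh]);
      else if (F.label != 1)
        mdot[f] += aF[f] * pc[F.owner];
    }
    green_gauss(pc, gpx, gpy, gpz, 1, 0.0, 0.0);
    for (int c = 0; c < nc; ++c) {
      u[c] -= Dcell[c] * gpx[c];
      v[c] -= Dcell[c] * gpy[c];
      w[c] -= Dcell[c] * gpz[c];
    }

    // --- residual scaling and convergence -------------------------------
    // self-scaled residuals: momentum by the current balance magnitude,
    // continuity by the current inlet mass flux (robust under warm starts)
    double qin = 0.0;
    for (int f = 0; f < nf; ++f)
      if (faces[f].neigh < 0 && faces[f].label == 2) qin -= mdot[f];
    res_u = res_mom[0] / (ref_mom + small);
    res_v = res_mom[1] / (ref_mom + small);
    res_w = res_mom[2] / (ref_mom + small);
    res_c = mass_res / (std::fabs(qin) + small);
    res_hist(outer, 0) = res_u; res_hist(outer, 1) = res_v;
    res_hist(outer, 2) = res_w; res_hist(outer, 3) = res_c;
    it_done = outer + 1;
    if (verbose && (outer % 25 == 0))
      Rcpp::Rcout << "outer " << outer << "  res u/v/w/c: " << res_u << " "
                  << res_v << " " << res_w << " " << res_c
                  << "  qin " << qin / rho << "\n";
    if (!std::isfinite(res_u + res_v + res_w + res_c))
      stop("3D solver diverged (non-finite residuals at iteration %d)", outer + 1);
    if (outer > 2 && res_u < tol && res_v < tol && res_w < tol && res_c < tol) {
      converged = true;
      break;
    }
    if (outer % 20 == 0) Rcpp::checkUserInterrupt();
  }

  // fluxes through the pressure boundaries
  double qin = 0.0, qout = 0.0;
  for (int f = 0; f < nf; ++f) {
    if (faces[f].neigh >= 0) continue;
    if (faces[f].label == 2) qin -= mdot[f] / rho;
    if (faces[f].label == 3) qout += mdot[f] / rho;
  }

  NumericMatrix u_out(nc, 3);
  NumericVector p_out_v(nc), vol_out(nc);
  NumericMatrix cc_out(nc, 3);
  for (int c = 0; c < nc; ++c) {
    u_out(c, 0) = u[c]; u_out(c, 1) = v[c]; u_out(c, 2) = w[c];
    p_out_v[c] = p[c]; vol_out[c] = vol[c];
    cc_out(c, 0) = ccx[c]; cc_out(c, 1) = ccy[c]; cc_out(c, 2) = ccz[c];
  }

  return List::create(
    _["u"] = u_out, _["p"] = p_out_v,
    _["cell_volume"] = vol_out, _["cell_centroid"] = cc_out,
    _["Q_in"] = qin, _["Q_out"] = qout,
    _["iterations"] = it_done, _["converged"] = converged,
    _["residuals"] = res_hist(Range(0, std::max(it_done - 1, 0)), _));
}
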