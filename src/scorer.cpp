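// Compiled core of the hydration-site scorer.
//
// The score of a probe position p is built from interaction terms of every
// atom within the receptive radius: a distance term per atom plus one angle
// term per bonded neighbour, pooled per atom and then across atoms by the
// statistical reduction (sum/avg/max/std -> PolyNN).  Placement and training
// both need exact derivatives, so the backward pass is hand-derived here:
// gradients w.r.t. the probe position, w.r.t. environment water positions
// (for joint refinement), and w.r.t. every parameter (for training).
//
// Summation order is canonical (protein atoms by storage order, then waters),
// so results are bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double WORST_SCORE = 1.0;   // empty receptive field

// ---------------------------------------------------------------------------
// PolyNN: x1 = Swish(W0 x0 + b0); x2 = exp(W1 log(1+x1)) - 1; x3 = W2 x2.
// Swish(z) >= -0.2785 guarantees 1 + x1 > 0, so the log is always defined.

struct Poly {
  mat W0, W1, W2;
  vec b0;
};

static Poly get_poly(const Rcpp::List& L) {
  Poly P;
  P.W0 = Rcpp::as<mat>(L["W0"]);
  P.b0 = Rcpp::as<vec>(L["b0"]);
  P.W1 = Rcpp::as<mat>(L["W1"]);
  P.W2 = Rcpp::as<mat>(L["W2"]);
  return P;
}

struct PolyGrad {
  mat W0, W1, W2;
  vec b0;
  void init(const Poly& P) {
    W0.zeros(size(P.W0));
    W1.zeros(size(P.W1));
    W2.zeros(size(P.W2));
    b0.zeros(size(P.b0));
  }
  Rcpp::List as_list() const {
    return Rcpp::List::create(Rcpp::Named("W0") = W0, Rcpp::Named("b0") = b0,
                              Rcpp::Named("W1") = W1, Rcpp::Named("W2") = W2);
  }
};

struct PolyCache {
  vec x0, z, s, x1, l, ea, x2;
};

static vec poly_fwd(const Poly& P, const vec& x0, PolyCache& C) {
  C.x0 = x0;
  C.z = P.W0 * x0 + P.b0;
  C.s = 1.0 / (1.0 + exp(-C.z));
  C.x1 = C.z % C.s;
  C.l = log1p(C.x1);
  vec a = P.W1 * C.l;
  C.ea = exp(a);
  C.x2 = C.ea - 1.0;
  return P.W2 * C.x2;
}

// returns gradient w.r.t. x0; accumulates parameter gradients when G != NULL
static vec poly_bwd(const Poly& P, const PolyCache& C, const vec& g3,
                    PolyGrad* G) {
  vec g2 = P.W2.t() * g3;
  if (G) G->W2 += g3 * C.x2.t();
  vec ga = g2 % C.ea;
  if (G) G->W1 += ga * C.l.t();
  vec gl = P.W1.t() * ga;
  vec g1 = gl / (1.0 + C.x1);
  vec gz = g1 % (C.s + C.z % C.s % (1.0 - C.s));
  if (G) {
    G->W0 += gz * C.x0.t();
    G->b0 += gz;
  }
  return P.W0.t() * gz;
}

// ---------------------------------------------------------------------------
// Statistical reduction over the columns of X (each column one input vector).

struct RedCache {
  mat X;
  vec sum, avg, mx, sd;
  uvec imax;
  int M;
};

static vec reduce_fwd(const mat& X, RedCache& C) {
  C.X = X;
  C.M = X.n_cols;
  C.sum = arma::sum(X, 1);
  C.avg = C.sum / C.M;
  C.imax = index_max(X, 1);          // first index on ties
  C.mx = max(X, 1);
  mat D = X.each_col() - C.avg;
  C.sd = sqrt(arma::sum(D % D, 1) / C.M);   // population std (divide by M)
  return join_cols(C.sum, join_cols(C.avg, join_cols(C.mx, C.sd)));
}

static mat reduce_bwd(const RedCache& C, const vec& gs) {
  const int n = C.X.n_rows, M = C.M;
  vec gsum = gs.subvec(0, n - 1);
  vec gavg = gs.subvec(n, 2 * n - 1);
  vec gmx = gs.subvec(2 * n, 3 * n - 1);
  vec gsd = gs.subvec(3 * n, 4 * n - 1);
  mat G(n, M);
  vec base = gsum + gavg / M;
  for (int i = 0; i < M; ++i) G.col(i) = base;
  for (int j = 0; j < n; ++j) {
    G(j, C.imax(j)) += gmx(j);
    if (C.sd(j) > 1e-12) {
      for (int i = 0; i < M; ++i)
        G(j, i) += gsd(j) * (C.X(j, i) - C.avg(j)) / (M * C.sd(j));
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Parameter and environment bundles.

struct Params {
  mat A;   // atom-type embeddings, one row per type
  mat B;   // bond-type embeddings
  Poly dist, ang, ared, fred, head;
  double R;   // receptive radius
};

static Params get_params(const Rcpp::List& L) {
  Params P;
  P.A = Rcpp::as<mat>(L["atom_embeddings"]);
  P.B = Rcpp::as<mat>(L["bond_embeddings"]);
  P.dist = get_poly(L["distance_term_net"]);
  P.ang = get_poly(L["angle_term_net"]);
  P.ared = get_poly(L["atom_reduce_net"]);
  P.fred = get_poly(L["final_reduce_net"]);
  P.head = get_poly(L["output_head"]);
  P.R = Rcpp::as<double>(L["receptive_radius"]);
  return P;
}

struct ParGrad {
  mat A, B;
  PolyGrad dist, ang, ared, fred, head;
  void init(const Params& P) {
    A.zeros(size(P.A));
    B.zeros(size(P.B));
    dist.init(P.dist);
    ang.init(P.ang);
    ared.init(P.ared);
    fred.init(P.fred);
    head.init(P.head);
  }
  Rcpp::List as_list() const {
    return Rcpp::List::create(
        Rcpp::Named("atom_embeddings") = A, Rcpp::Named("bond_embeddings") = B,
        Rcpp::Named("distance_term_net") = dist.as_list(),
        Rcpp::Named("angle_term_net") = ang.as_list(),
        Rcpp::Named("atom_reduce_net") = ared.as_list(),
        Rcpp::Named("final_reduce_net") = fred.as_list(),
        Rcpp::Named("output_head") = head.as_list());
  }
};

struct Env {
  mat P;                        // protein atoms, n x 3
  ivec ptype;                   // 0-based atom type ids
  ivec nptr, nidx, nbond;       // CSR bonded-neighbour lists (0-based)
  int wtype;                    // atom type id of a water oxygen
};

static Env get_env(const Rcpp::List& L) {
  Env E;
  E.P = Rcpp::as<mat>(L["P"]);
  E.ptype = Rcpp::as<ivec>(L["ptype"]);
  E.nptr = Rcpp::as<ivec>(L["nptr"]);
  E.nidx = Rcpp::as<ivec>(L["nidx"]);
  E.nbond = Rcpp::as<ivec>(L["nbond"]);
  E.wtype = Rcpp::as<int>(L["wtype"]);
  return E;
}

// ---------------------------------------------------------------------------
// Full score with optional backward pass.
//
// gp       : gradient w.r.t. p (filled when want_grad)
// gW       : gradient w.r.t. water positions, m x 3 (when want_grad)
// PG       : parameter gradients accumulated with outer seed `seed`
//            (seed = dLoss/dscore); when PG==NULL seed is 1.

struct TermGeom {
  int kind;        // 0 = distance, 1 = angle
  int atom;        // protein index, or -1
  int water;       // water index, or -1
  int nbr, bond;   // angle term: bonded neighbour index + bond type
  PolyCache pc;
};

struct AtomWork {
  std::vector<TermGeom> terms;
  RedCache red;
  PolyCache ared;
};

static double score_eval(const Params& par, const Env& env, const mat& Wt,
                         const vec& p, bool want_grad, double seed,
                         vec& gp, mat& gW, ParGrad* PG) {
  const int n = env.P.n_rows, m = Wt.n_rows;
  const int da = par.A.n_cols;
  const double R2 = par.R * par.R;

  std::vector<int> np, nw;   // protein / water neighbours (canonical order)
  for (int i = 0; i < n; ++i) {
    const double dx = env.P(i, 0) - p(0), dy = env.P(i, 1) - p(1),
                 dz = env.P(i, 2) - p(2);
    if (dx * dx + dy * dy + dz * dz <= R2) np.push_back(i);
  }
  for (int i = 0; i < m; ++i) {
    const double dx = Wt(i, 0) - p(0), dy = Wt(i, 1) - p(1),
                 dz = Wt(i, 2) - p(2);
    if (dx * dx + dy * dy + dz * dz <= R2) nw.push_back(i);
  }

  gp.zeros(3);
  gW.zeros(m, 3);
  const int K = np.size() + nw.size();
  if (K == 0) return WORST_SCORE;

  std::vector<AtomWork> work(K);
  const int dt = par.dist.W2.n_rows;   // interaction-term output width
  const int de = par.ared.W2.n_rows;   // interaction embedding width
  mat Emb(de, K);

  for (int k = 0; k < K; ++k) {
    AtomWork& aw = work[k];
    const bool is_w = k >= (int)np.size();
    const int idx = is_w ? nw[k - np.size()] : np[k];
    const rowvec qpos = is_w ? Wt.row(idx) : env.P.row(idx);
    const int qt = is_w ? env.wtype : env.ptype(idx);

    // distance term
    {
      TermGeom tg;
      tg.kind = 0;
      tg.atom = is_w ? -1 : idx;
      tg.water = is_w ? idx : -1;
      tg.nbr = tg.bond = -1;
      vec x0(da + 1);
      x0.subvec(0, da - 1) = par.A.row(qt).t();
      x0(da) = norm(p - qpos.t());
      vec out = poly_fwd(par.dist, x0, tg.pc);
      aw.terms.push_back(tg);
      if (aw.red.X.n_rows == 0) aw.red.X.set_size(dt, 0);
      aw.red.X.insert_cols(aw.red.X.n_cols, out);
    }
    // angle terms: one per bonded neighbour (protein atoms only; waters
    // are bond-less by construction)
    if (!is_w) {
      for (int t = env.nptr(idx); t < env.nptr(idx + 1); ++t) {
        const int r = env.nidx(t), bt = env.nbond(t);
        TermGeom tg;
        tg.kind = 1;
        tg.atom = idx;
        tg.water = -1;
        tg.nbr = r;
        tg.bond = bt;
        const int rt = env.ptype(r);
        const int db = par.B.n_cols;
        vec u = p - qpos.t();
        vec v = env.P.row(r).t() - qpos.t();
        double nu = norm(u), nv = norm(v);
        if (nu < 1e-9) nu = 1e-9;   // degenerate p == q guard
        if (nv < 1e-9) nv = 1e-9;
        const double cth = dot(u, v) / (nu * nv);
        vec x0(2 * da + db + 1);
        x0.subvec(0, da - 1) = par.A.row(qt).t();
        x0.subvec(da, 2 * da - 1) = par.A.row(rt).t();
        x0.subvec(2 * da, 2 * da + db - 1) = par.B.row(bt).t();
        x0(2 * da + db) = cth;
        vec out = poly_fwd(par.ang, x0, tg.pc);
        aw.terms.push_back(tg);
        aw.red.X.insert_cols(aw.red.X.n_cols, out);
      }
    }
    const vec stats = reduce_fwd(aw.red.X, aw.red);
    Emb.col(k) = poly_fwd(par.ared, stats, aw.ared);
  }

  RedCache fred_red;
  const vec fstats = reduce_fwd(Emb, fred_red);
  PolyCache fred_pc, head_pc;
  const vec h = poly_fwd(par.fred, fstats, fred_pc);
  const vec out = poly_fwd(par.head, h, head_pc);
  const double value = out(0);

  if (!want_grad && !PG) return value;

  // ----- backward -----
  PolyGrad* Ghead = PG ? &PG->head : 0;
  PolyGrad* Gfred = PG ? &PG->fred : 0;
  PolyGrad* Gared = PG ? &PG->ared : 0;
  PolyGrad* Gdist = PG ? &PG->dist : 0;
  PolyGrad* Gang = PG ? &PG->ang : 0;

  vec gout(1);
  gout(0) = seed;
  vec gh = poly_bwd(par.head, head_pc, gout, Ghead);
  vec gfstats = poly_bwd(par.fred, fred_pc, gh, Gfred);
  mat gEmb = reduce_bwd(fred_red, gfstats);

  const int db = par.B.n_cols;
  for (int k = 0; k < K; ++k) {
    AtomWork& aw = work[k];
    vec gstats = poly_bwd(par.ared, aw.ared, gEmb.col(k), Gared);
    mat gT = reduce_bwd(aw.red, gstats);
    for (size_t t = 0; t < aw.terms.size(); ++t) {
      TermGeom& tg = aw.terms[t];
      vec gx0;
      if (tg.kind == 0) {
        gx0 = poly_bwd(par.dist, tg.pc, gT.col(t), Gdist);
        if (PG) {
          const int qt = tg.water >= 0 ? env.wtype : env.ptype(tg.atom);
          PG->A.row(qt) += gx0.subvec(0, da - 1).t();
        }
        const double gd = gx0(da);
        const rowvec qpos =
            tg.water >= 0 ? Wt.row(tg.water) : env.P.row(tg.atom);
        vec u = p - qpos.t();
        double d = norm(u);
        if (d < 1e-9) d = 1e-9;
        gp += gd * u / d;
        if (tg.water >= 0) gW.row(tg.water) += (-gd / d) * u.t();
      } else {
        gx0 = poly_bwd(par.ang, tg.pc, gT.col(t), Gang);
        const int qt = env.ptype(tg.atom), rt = env.ptype(tg.nbr);
        if (PG) {
          PG->A.row(qt) += gx0.subvec(0, da - 1).t();
          PG->A.row(rt) += gx0.subvec(da, 2 * da - 1).t();
          PG->B.row(tg.bond) += gx0.subvec(2 * da, 2 * da + db - 1).t();
        }
        const double gc = gx0(2 * da + db);
        vec u = p - env.P.row(tg.atom).t();
        vec v = env.P.row(tg.nbr).t() - env.P.row(tg.atom).t();
        double nu = norm(u), nv = norm(v);
        if (nu < 1e-9) nu = 1e-9;
        if (nv < 1e-9) nv = 1e-9;
        const double cth = dot(u, v) / (nu * nv);
        // d cos / d u = v/(|u||v|) - cos * u/|u|^2
        gp += gc * (v / (nu * nv) - cth * u / (nu * nu));
      }
    }
  }
  if (want_grad && seed != 1.0) {
    gp *= seed;
    gW *= seed;
  }
  return value;
}

// ---------------------------------------------------------------------------
// Exported entry points.

// [[Rcpp::export]]
Rcpp::List cpp_score(Rcpp::List params, Rcpp::List env, arma::mat waters,
                     arma::vec p, bool grad = true) {
  Params par = get_params(params);
  Env E = get_env(env);
  vec gp;
  mat gW;
  double v = score_eval(par, E, waters, p, grad, 1.0, gp, gW, 0);
  return Rcpp::List::create(Rcpp::Named("value") = v,
                            Rcpp::Named("grad_p") = gp,
                            Rcpp::Named("grad_waters") = gW);
}

// [[Rcpp::export]]
arma::vec cpp_score_many(Rcpp::List params, Rcpp::List env, arma::mat waters,
                         arma::mat probes) {
  Params par = get_params(params);
  Env E = get_env(env);
  vec gp;
  mat gW;
  vec out(probes.n_rows);
  for (uword i = 0; i < probes.n_rows; ++i)
    out(i) = score_eval(par, E, waters, probes.row(i).t(), false, 1.0, gp, gW, 0);
  return out;
}

// Gradient descent on probe positions, each start independent, environment
// fixed.  Backtracking step control; positions are clamped to an escape ball
// around `centers` (the grid box centers; equal to `starts` unless warm
// starting from a previously optimized position).
// [[Rcpp::export]]
Rcpp::List cpp_optimize(Rcpp::List params, Rcpp::List env, arma::mat waters,
                        arma::mat starts, arma::mat centers, double max_step,
                        int max_iter, double tol, double escape) {
  Params par = get_params(params);
  Env E = get_env(env);
  const int k = starts.n_rows;
  mat pos(k, 3);
  vec val(k);
  ivec iters(k);
  vec gp;
  mat gW;
  for (int i = 0; i < k; ++i) {
    vec cur = starts.row(i).t();
    double f = score_eval(par, E, waters, cur, true, 1.0, gp, gW, 0);
    double lr = 0.1;
    int it = 0;
    while (it < max_iter) {
      ++it;
      double gn = norm(gp);
      if (gn < 1e-12) break;
      vec step = -lr * gp;
      double sn = norm(step);
      if (sn > max_step) step *= max_step / sn;
      vec cand = cur + step;
      vec off = cand - centers.row(i).t();
      double on = norm(off);
      if (on > escape) cand = centers.row(i).t() + off * (escape / on);
      vec gp2;
      mat gW2;
      double fc = score_eval(par, E, waters, cand, true, 1.0, gp2, gW2, 0);
      if (fc < f - 1e-12) {
        double moved = norm(cand - cur);
        cur = cand;
        f = fc;
        gp = gp2;
        lr = std::min(lr * 1.3, 1.0);
        if (moved < tol) break;
      } else {
        lr *= 0.5;
        if (lr < 1e-4) break;
      }
    }
    pos.row(i) = cur.t();
    val(i) = f;
    iters(i) = it;
  }
  return Rcpp::List::create(Rcpp::Named("positions") = pos,
                            Rcpp::Named("scores") = val,
                            Rcpp::Named("iterations") = iters);
}

// Weighted squared-error data loss and parameter gradients over a minibatch.
// y holds labels already passed through the Norm squashing.  The L2 penalty
// is added on the R side.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::List envs, Rcpp::List winst,
                         arma::ivec sid, arma::mat probes, arma::vec y,
                         arma::vec w) {
  Params par = get_params(params);
  std::vector<Env> E;
  for (int s = 0; s < envs.size(); ++s) E.push_back(get_env(envs[s]));
  ParGrad PG;
  PG.init(par);
  const int N = probes.n_rows;
  vec preds(N);
  double loss = 0.0;
  vec gp;
  mat gW;
  for (int i = 0; i < N; ++i) {
    const Env& e = E[sid(i) - 1];
    mat Wt = Rcpp::as<mat>(winst[i]);
    // forward once to get the prediction, then backward with the loss seed
    double pred = score_eval(par, e, Wt, probes.row(i).t(), false, 1.0, gp, gW, 0);
    const double r = pred - y(i);
    loss += w(i) * r * r;
    const double seed = 2.0 * w(i) * r;
    if (seed != 0.0)
      score_eval(par, e, Wt, probes.row(i).t(), false, seed, gp, gW, &PG);
    preds(i) = pred;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("predictions") = preds,
                            Rcpp::Named("gradients") = PG.as_list());
}

// Joint refinement: gradient descent on all movable water positions under
// F(W) = sum_j score(p_j | protein + fixed + W_{-j}), including the cross
// terms through the receptive fields of the other movable waters.  `fixed`
// holds waters that belong to the structure and do not move.
// [[Rcpp::export]]
Rcpp::List cpp_joint_refine_fixed(Rcpp::List params, Rcpp::List env,
                                  arma::mat fixed, arma::mat waters,
                                  int max_iter, double max_step, double tol) {
  Params par = get_params(params);
  Env E = get_env(env);
  const int K = waters.n_rows;
  const int nf = fixed.n_rows;
  mat W = waters;

  auto eval = [&](const mat& Wc, mat* G, vec* scores) -> double {
    double F = 0.0;
    if (G) G->zeros(K, 3);
    for (int j = 0; j < K; ++j) {
      mat others(nf + K - 1, 3);
      for (int t = 0; t < nf; ++t) others.row(t) = fixed.row(t);
      for (int t = 0, r = nf; t < K; ++t)
        if (t != j) others.row(r++) = Wc.row(t);
      vec gp;
      mat gW;
      double v = score_eval(par, E, others, Wc.row(j).t(), G != 0, 1.0, gp,
                            gW, 0);
      F += v;
      if (scores) (*scores)(j) = v;
      if (G) {
        G->row(j) += gp.t();
        for (int t = 0, r = nf; t < K; ++t)
          if (t != j) G->row(t) += gW.row(r++);
      }
    }
    return F;
  };

  vec scores(K);
  if (K == 0)
    return Rcpp::List::create(Rcpp::Named("waters") = W,
                              Rcpp::Named("scores") = scores);
  mat G;
  double F = eval(W, &G, &scores);
  double lr = 0.05;
  for (int it = 0; it < max_iter; ++it) {
    mat step = -lr * G;
    for (int j = 0; j < K; ++j) {
      double sn = norm(step.row(j));
      if (sn > max_step) step.row(j) *= max_step / sn;
    }
    mat cand = W + step;
    mat G2;
    vec sc2(K);
    double Fc = eval(cand, &G2, &sc2);
    if (Fc < F - 1e-12) {
      double moved = norm(cand - W, "fro");
      W = cand;
      F = Fc;
      G = G2;
      scores = sc2;
      lr = std::min(lr * 1.3, 0.5);
      if (moved < tol) break;
    } else {
      lr *= 0.5;
      if (lr < 1e-4) break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("waters") = W,
                            Rcpp::Named("scores") = scores);
}
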