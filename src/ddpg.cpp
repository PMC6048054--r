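// DDPG engine: dense two-hidden-layer actor/critic networks, target copies,
// Adam, Ornstein-Uhlenbeck exploration and a FIFO replay buffer.  All
// randomness is drawn from R's RNG so that set.seed() makes runs reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// Multilayer perceptron with exactly two ReLU hidden layers.
// Actor heads are squashed with a_max * tanh(z); critic heads are linear.
// ---------------------------------------------------------------------------
struct MLP {
  mat W1, W2, W3;       // (in x h1), (h1 x h2), (h2 x out)
  rowvec b1, b2, b3;
  int in = 0, h1 = 0, h2 = 0, out = 0;

  void init(int in_, int h1_, int h2_, int out_, double final_w = 3e-3) {
    in = in_; h1 = h1_; h2 = h2_; out = out_;
    auto u = [](int r, int c, double a) {
      mat M(r, c);
      for (uword i = 0; i < M.n_elem; ++i) M(i) = (2.0 * unif_rand() - 1.0) * a;
      return M;
    };
    double a1 = 1.0 / std::sqrt((double)in), a2 = 1.0 / std::sqrt((double)h1);
    W1 = u(in, h1, a1);  b1 = u(1, h1, a1);
    W2 = u(h1, h2, a2);  b2 = u(1, h2, a2);
    W3 = u(h2, out, final_w); b3 = u(1, out, final_w);
  }

  int n_params() const {
    return in * h1 + h1 + h1 * h2 + h2 + h2 * out + out;
  }

  vec flatten() const {
    return join_cols(join_cols(vectorise(W1), vectorise(b1)),
                     join_cols(join_cols(vectorise(W2), vectorise(b2)),
                               join_cols(vectorise(W3), vectorise(b3))));
  }

  void unflatten(const vec& p) {
    if ((int)p.n_elem != n_params()) Rcpp::stop("parameter vector has wrong length");
    uword k = 0;
    auto take = [&](uword n) { vec v = p.subvec(k, k + n - 1); k += n; return v; };
    W1 = reshape(take(in * h1), in, h1);
    b1 = take(h1).t();
    W2 = reshape(take(h1 * h2), h1, h2);
    b2 = take(h2).t();
    W3 = reshape(take(h2 * out), h2, out);
    b3 = take(out).t();
  }
};

struct Cache {                 // forward-pass activations kept for backprop
  mat X, Z1, H1, Z2, H2, Z3, T;  // T = tanh(Z3) for squashed heads
};

struct Grads {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
};

static inline void relu_copy(const mat& z, mat& h) {
  h.set_size(size(z));
  const double* pz = z.memptr();
  double* ph = h.memptr();
  for (uword i = 0; i < z.n_elem; ++i) ph[i] = pz[i] > 0.0 ? pz[i] : 0.0;
}

static inline void relu_mask(mat& d, const mat& z) {
  double* pd = d.memptr();
  const double* pz = z.memptr();
  for (uword i = 0; i < d.n_elem; ++i) if (pz[i] <= 0.0) pd[i] = 0.0;
}

static mat mlp_forward(const MLP& n, const mat& X, Cache& c,
                       bool squash, double amax) {
  c.X = X;
  c.Z1 = X * n.W1;  c.Z1.each_row() += n.b1;  relu_copy(c.Z1, c.H1);
  c.Z2 = c.H1 * n.W2; c.Z2.each_row() += n.b2; relu_copy(c.Z2, c.H2);
  c.Z3 = c.H2 * n.W3; c.Z3.each_row() += n.b3;
  if (squash) { c.T = tanh(c.Z3); return amax * c.T; }
  return c.Z3;
}

static mat mlp_forward_nograd(const MLP& n, const mat& X, bool squash, double amax) {
  mat H1 = X * n.W1;  H1.each_row() += n.b1;  relu_mask(H1, H1);
  mat H2 = H1 * n.W2; H2.each_row() += n.b2;  relu_mask(H2, H2);
  mat Z3 = H2 * n.W3; Z3.each_row() += n.b3;
  if (squash) return amax * tanh(Z3);
  return Z3;
}

// Backprop dOut (gradient w.r.t. the pre-squash output for critics, or w.r.t.
// the squashed output for actors) into parameter gradients; optionally also
// returns the gradient with respect to the input matrix.
static void mlp_backward_ws(const MLP& n, const Cache& c, mat dOut,
                            bool squash, double amax, Grads& g,
                            mat* dX = nullptr) {
  if (squash) dOut = dOut % (amax * (1.0 - square(c.T)));
  g.W3 = c.H2.t() * dOut;           g.b3 = sum(dOut, 0);
  mat dZ2 = dOut * n.W3.t();
  relu_mask(dZ2, c.Z2);
  g.W2 = c.H1.t() * dZ2;            g.b2 = sum(dZ2, 0);
  mat dZ1 = dZ2 * n.W2.t();
  relu_mask(dZ1, c.Z1);
  g.W1 = c.X.t() * dZ1;             g.b1 = sum(dZ1, 0);
  if (dX) *dX = dZ1 * n.W1.t();
}

static Grads mlp_backward(const MLP& n, const Cache& c, const mat& dOut,
                          bool squash, double amax, mat* dX = nullptr) {
  Grads g;
  mlp_backward_ws(n, c, dOut, squash, amax, g, dX);
  return g;
}

static vec grads_flatten(const Grads& g) {
  return join_cols(join_cols(vectorise(g.W1), vectorise(g.b1)),
                   join_cols(join_cols(vectorise(g.W2), vectorise(g.b2)),
                             join_cols(vectorise(g.W3), vectorise(g.b3))));
}

// ---------------------------------------------------------------------------
// Adam optimiser over the six tensors of one MLP.
// ---------------------------------------------------------------------------
struct Adam {
  mat mW1, mW2, mW3, vW1, vW2, vW3;
  rowvec mb1, mb2, mb3, vb1, vb2, vb3;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const MLP& n) {
    mW1 = zeros(size(n.W1)); vW1 = mW1;
    mW2 = zeros(size(n.W2)); vW2 = mW2;
    mW3 = zeros(size(n.W3)); vW3 = mW3;
    mb1 = zeros<rowvec>(n.b1.n_elem); vb1 = mb1;
    mb2 = zeros<rowvec>(n.b2.n_elem); vb2 = mb2;
    mb3 = zeros<rowvec>(n.b3.n_elem); vb3 = mb3;
    t = 0;
  }

  template <typename T>
  void upd(T& p, T& m, T& v, const T& g, double lr, double c1, double c2) {
    double* pp = p.memptr();
    double* pm = m.memptr();
    double* pv = v.memptr();
    const double* pg = g.memptr();
    const double sc2 = std::sqrt(1.0 / c2);
    for (uword i = 0; i < p.n_elem; ++i) {
      pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
      pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
      pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i]) * sc2 + eps);
    }
  }

  void step(MLP& n, const Grads& g, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(beta1, (double)t);
    double c2 = 1.0 - std::pow(beta2, (double)t);
    upd(n.W1, mW1, vW1, g.W1, lr, c1, c2);
    upd(n.W2, mW2, vW2, g.W2, lr, c1, c2);
    upd(n.W3, mW3, vW3, g.W3, lr, c1, c2);
    upd(n.b1, mb1, vb1, g.b1, lr, c1, c2);
    upd(n.b2, mb2, vb2, g.b2, lr, c1, c2);
    upd(n.b3, mb3, vb3, g.b3, lr, c1, c2);
  }
};

// ---------------------------------------------------------------------------
// FIFO replay buffer with uniform minibatch sampling (without replacement
// within a batch).
// ---------------------------------------------------------------------------
struct ReplayBuffer {
  // transitions are stored as columns so minibatch gathers stay contiguous
  mat S, A, S2;
  vec R, D;
  int capacity = 0, sdim = 0, adim = 0, size = 0, pos = 0;

  void init(int cap, int sd, int ad) {
    capacity = cap; sdim = sd; adim = ad; size = 0; pos = 0;
    S.set_size(sd, cap); A.set_size(ad, cap); S2.set_size(sd, cap);
    R.set_size(cap); D.set_size(cap);
  }

  void push(const rowvec& s, const rowvec& a, double r, const rowvec& s2, double d) {
    S.col(pos) = s.t(); A.col(pos) = a.t(); S2.col(pos) = s2.t();
    R(pos) = r; D(pos) = d;
    pos = (pos + 1) % capacity;
    if (size < capacity) ++size;
  }

  // batch rows = transitions (gathered from contiguous columns)
  void gather(const uvec& idx, mat& Sb, mat& Ab, vec& Rb, mat& S2b, vec& Db) const {
    Sb = mat(S.cols(idx)).t();
    Ab = mat(A.cols(idx)).t();
    S2b = mat(S2.cols(idx)).t();
    Rb = R.elem(idx);
    Db = D.elem(idx);
  }

  uvec sample_idx(int n) const {
    if (size == 0) Rcpp::stop("cannot sample from an empty replay buffer");
    if (n > size) Rcpp::stop("sample size exceeds buffer size");
    uvec idx(n);
    // uniform without replacement; n is small so a linear membership scan is fine
    for (int i = 0; i < n; ++i) {
      uword cand;
      bool dup;
      do {
        cand = (uword)std::floor(unif_rand() * size);
        if (cand >= (uword)size) cand = size - 1;
        dup = false;
        for (int j = 0; j < i; ++j) if (idx(j) == cand) { dup = true; break; }
      } while (dup);
      idx(i) = cand;
    }
    return idx;
  }
};

// ---------------------------------------------------------------------------
// Ornstein-Uhlenbeck exploration noise.
// ---------------------------------------------------------------------------
struct OUNoise {
  vec x;
  double theta = 0.15, sigma = 0.2, dt = 1.0;

  void init(int dim, double th, double sg, double dt_) {
    x = zeros(dim); theta = th; sigma = sg; dt = dt_;
  }
  vec step() {
    for (uword i = 0; i < x.n_elem; ++i)
      x(i) += theta * (0.0 - x(i)) * dt + sigma * std::sqrt(dt) * norm_rand();
    return x;
  }
  void reset() { x.zeros(); }
};

// ---------------------------------------------------------------------------
// Agent: one actor-critic pair with target copies.
// ---------------------------------------------------------------------------
struct Agent {
  MLP actor, critic, t_actor, t_critic;
  Adam opt_actor, opt_critic;
  OUNoise noise;
  ReplayBuffer buf;
  int sdim, adim;
  double amax, gamma, tau, lr;
  int batch;
  double eps_uniform = 0.1;  // chance of a uniform random action while exploring
  double actor_wd = 0.0;     // decoupled actor weight decay (AdamW style)
  mat wS, wA, wS2;          // minibatch workspace
  vec wR, wD;
  Cache c_td, c_tq, c_cr, c_aa, c_aq;  // persistent forward caches
  Grads g_cr, g_ac;
  mat wXc;                  // [state, scaled action] critic input workspace

  Agent(int sd, int ad, int h1, int h2, double amax_, double gamma_,
        double tau_, double lr_, int capacity, int batch_,
        double ou_theta, double ou_sigma, double ou_dt, double eps_uniform_,
        double actor_wd_)
      : sdim(sd), adim(ad), amax(amax_), gamma(gamma_), tau(tau_), lr(lr_),
        batch(batch_), eps_uniform(eps_uniform_), actor_wd(actor_wd_) {
    actor.init(sd, h1, h2, ad);
    critic.init(sd + ad, h1, h2, 1);
    t_actor = actor;          // targets start equal to the live networks
    t_critic = critic;
    opt_actor.init(actor);
    opt_critic.init(critic);
    noise.init(ad, ou_theta, ou_sigma, ou_dt);
    buf.init(capacity, sd, ad);
  }

  rowvec act(const rowvec& s, bool explore) {
    mat a = mlp_forward_nograd(actor, s, true, amax);
    rowvec out = a.row(0);
    if (explore) {
      vec n = noise.step();
      out += n.t();
      // occasional uniform actions keep off-policy coverage of the whole
      // action range once the policy has committed to one extreme
      for (uword j = 0; j < out.n_elem; ++j)
        if (unif_rand() < eps_uniform)
          out(j) = (2.0 * unif_rand() - 1.0) * amax;
      out = clamp(out, -amax, amax);
    }
    return out;
  }

  // the critic always sees actions scaled to [-1, 1] so that action and
  // state inputs are comparably conditioned; buffers store raw actions
  void critic_input(const mat& S, const mat& A, mat& out) const {
    out.set_size(S.n_rows, S.n_cols + A.n_cols);
    out.cols(0, S.n_cols - 1) = S;
    out.cols(S.n_cols, out.n_cols - 1) = A / amax;
  }

  vec td_target(const mat& S2, const vec& R, const vec& D) {
    mat A2 = mlp_forward(t_actor, S2, c_td, true, amax);
    critic_input(S2, A2, wXc);
    mat Q2 = mlp_forward(t_critic, wXc, c_tq, false, 0.0);
    return R + gamma * (1.0 - D) % Q2.col(0);
  }

  // One Adam step on the critic; returns the pre-update TD loss.
  double critic_update(const mat& S, const mat& A, const vec& R,
                       const mat& S2, const vec& D) {
    vec y = td_target(S2, R, D);
    critic_input(S, A, wXc);
    mat Q = mlp_forward(critic, wXc, c_cr, false, 0.0);
    vec err = Q.col(0) - y;
    double loss = mean(square(err));
    mat dOut = 2.0 * err / (double)err.n_elem;
    mlp_backward_ws(critic, c_cr, dOut, false, 0.0, g_cr);
    opt_critic.step(critic, g_cr, lr);
    return loss;
  }

  // One Adam ascent step on the actor along the deterministic policy
  // gradient; returns mean_s Q(s, mu(s)) before the update.
  double actor_update(const mat& S) {
    mat A = mlp_forward(actor, S, c_aa, true, amax);
    critic_input(S, A, wXc);
    mat Q = mlp_forward(critic, wXc, c_aq, false, 0.0);
    double J = mean(Q.col(0));
    mat dOut = ones(Q.n_rows, 1) / (double)Q.n_rows;
    // backprop through the critic to its action inputs only
    mat dZ2 = dOut * critic.W3.t();
    relu_mask(dZ2, c_aq.Z2);
    mat dZ1 = dZ2 * critic.W2.t();
    relu_mask(dZ1, c_aq.Z1);
    mat dA = dZ1 * critic.W1.rows(sdim, sdim + adim - 1).t() / amax;
    mlp_backward_ws(actor, c_aa, dA, true, amax, g_ac);
    Grads& g = g_ac;
    // ascent: negate
    g.W1 *= -1.0; g.W2 *= -1.0; g.W3 *= -1.0;
    g.b1 *= -1.0; g.b2 *= -1.0; g.b3 *= -1.0;
    opt_actor.step(actor, g, lr);
    if (actor_wd > 0.0) {
      // decoupled weight decay: directions without persistent policy-gradient
      // support shrink towards zero (and the action towards mid-range)
      double f = 1.0 - lr * actor_wd;
      actor.W1 *= f; actor.W2 *= f; actor.W3 *= f;
      actor.b1 *= f; actor.b2 *= f; actor.b3 *= f;
    }
    return J;
  }

  void polyak() {
    const double om = 1.0 - tau;
    auto mix = [&](mat& t, const mat& l) {
      double* pt = t.memptr(); const double* pl = l.memptr();
      for (uword i = 0; i < t.n_elem; ++i) pt[i] = tau * pl[i] + om * pt[i];
    };
    auto mixr = [&](rowvec& t, const rowvec& l) {
      double* pt = t.memptr(); const double* pl = l.memptr();
      for (uword i = 0; i < t.n_elem; ++i) pt[i] = tau * pl[i] + om * pt[i];
    };
    mix(t_actor.W1, actor.W1);   mixr(t_actor.b1, actor.b1);
    mix(t_actor.W2, actor.W2);   mixr(t_actor.b2, actor.b2);
    mix(t_actor.W3, actor.W3);   mixr(t_actor.b3, actor.b3);
    mix(t_critic.W1, critic.W1); mixr(t_critic.b1, critic.b1);
    mix(t_critic.W2, critic.W2); mixr(t_critic.b2, critic.b2);
    mix(t_critic.W3, critic.W3); mixr(t_critic.b3, critic.b3);
  }

  MLP& net(int which) {
    switch (which) {
      case 0: return actor;
      case 1: return critic;
      case 2: return t_actor;
      default: return t_critic;
    }
  }
};

typedef Rcpp::XPtr<Agent> AgentPtr;

// [[Rcpp::export]]
SEXP cpp_agent_new(int sdim, int adim, int h1, int h2, double amax,
                   double gamma, double tau, double lr, int capacity,
                   int batch, double ou_theta, double ou_sigma, double ou_dt,
                   double eps_uniform, double actor_wd) {
  Agent* a = new Agent(sdim, adim, h1, h2, amax, gamma, tau, lr, capacity,
                       batch, ou_theta, ou_sigma, ou_dt, eps_uniform, actor_wd);
  return AgentPtr(a, true);
}

// [[Rcpp::export]]
arma::rowvec cpp_agent_act(SEXP ptr, const arma::rowvec& state, bool explore) {
  AgentPtr a(ptr);
  if ((int)state.n_elem != a->sdim) Rcpp::stop("state dimension mismatch");
  return a->act(state, explore);
}

// [[Rcpp::export]]
void cpp_agent_push(SEXP ptr, const arma::rowvec& s, const arma::rowvec& a,
                    double r, const arma::rowvec& s2, double done) {
  AgentPtr ag(ptr);
  if ((int)s.n_elem != ag->sdim || (int)s2.n_elem != ag->sdim)
    Rcpp::stop("state dimension mismatch");
  if ((int)a.n_elem != ag->adim) Rcpp::stop("action dimension mismatch");
  ag->buf.push(s, a, r, s2, done);
}

// [[Rcpp::export]]
int cpp_agent_buffer_size(SEXP ptr) { return AgentPtr(ptr)->buf.size; }

// [[Rcpp::export]]
Rcpp::List cpp_agent_sample(SEXP ptr, int n) {
  AgentPtr a(ptr);
  uvec idx = a->buf.sample_idx(n);
  mat S, A, S2; vec R, D;
  a->buf.gather(idx, S, A, R, S2, D);
  return Rcpp::List::create(
      Rcpp::Named("S") = S, Rcpp::Named("A") = A,
      Rcpp::Named("R") = Rcpp::NumericVector(R.begin(), R.end()),
      Rcpp::Named("S2") = S2,
      Rcpp::Named("D") = Rcpp::NumericVector(D.begin(), D.end()));
}

// [[Rcpp::export]]
arma::vec cpp_agent_td_target(SEXP ptr, const arma::mat& S2,
                              const arma::vec& R, const arma::vec& D) {
  return AgentPtr(ptr)->td_target(S2, R, D);
}

// [[Rcpp::export]]
double cpp_agent_critic_update(SEXP ptr, const arma::mat& S, const arma::mat& A,
                               const arma::vec& R, const arma::mat& S2,
                               const arma::vec& D) {
  return AgentPtr(ptr)->critic_update(S, A, R, S2, D);
}

// [[Rcpp::export]]
double cpp_agent_actor_update(SEXP ptr, const arma::mat& S) {
  return AgentPtr(ptr)->actor_update(S);
}

// [[Rcpp::export]]
void cpp_agent_polyak(SEXP ptr) { AgentPtr(ptr)->polyak(); }

// Sample a minibatch internally and run critic, actor and Polyak updates.
// Returns c(critic loss, mean Q) or c(NA, NA) when the buffer is too small.
// [[Rcpp::export]]
arma::vec cpp_agent_train_step(SEXP ptr) {
  AgentPtr a(ptr);
  vec out(2, fill::value(datum::nan));
  if (a->buf.size < a->batch) return out;
  uvec idx = a->buf.sample_idx(a->batch);
  a->buf.gather(idx, a->wS, a->wA, a->wR, a->wS2, a->wD);
  out(0) = a->critic_update(a->wS, a->wA, a->wR, a->wS2, a->wD);
  out(1) = a->actor_update(a->wS);
  a->polyak();
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_agent_get_params(SEXP ptr, int which) {
  return AgentPtr(ptr)->net(which).flatten();
}

// [[Rcpp::export]]
void cpp_agent_set_params(SEXP ptr, int which, const arma::vec& p) {
  AgentPtr(ptr)->net(which).unflatten(p);
}

// [[Rcpp::export]]
double cpp_agent_critic_loss(SEXP ptr, const arma::mat& S, const arma::mat& A,
                             const arma::vec& R, const arma::mat& S2,
                             const arma::vec& D) {
  AgentPtr a(ptr);
  vec y = a->td_target(S2, R, D);
  mat Q = mlp_forward_nograd(a->critic, join_rows(S, A / a->amax), false, 0.0);
  return mean(square(Q.col(0) - y));
}

// [[Rcpp::export]]
double cpp_agent_actor_objective(SEXP ptr, const arma::mat& S) {
  AgentPtr a(ptr);
  mat A = mlp_forward_nograd(a->actor, S, true, a->amax);
  mat Q = mlp_forward_nograd(a->critic, join_rows(S, A / a->amax), false, 0.0);
  return mean(Q.col(0));
}

// Analytic gradient of the critic TD loss w.r.t. critic parameters.
// [[Rcpp::export]]
arma::vec cpp_agent_critic_grad(SEXP ptr, const arma::mat& S, const arma::mat& A,
                                const arma::vec& R, const arma::mat& S2,
                                const arma::vec& D) {
  AgentPtr a(ptr);
  vec y = a->td_target(S2, R, D);
  Cache c;
  mat Q = mlp_forward(a->critic, join_rows(S, A / a->amax), c, false, 0.0);
  mat dOut = 2.0 * (Q.col(0) - y) / (double)y.n_elem;
  Grads g = mlp_backward(a->critic, c, dOut, false, 0.0);
  return grads_flatten(g);
}

// Analytic gradient of mean_s Q(s, mu(s)) w.r.t. actor parameters.
// [[Rcpp::export]]
arma::vec cpp_agent_actor_grad(SEXP ptr, const arma::mat& S) {
  AgentPtr a(ptr);
  Cache ca, cc;
  mat A = mlp_forward(a->actor, S, ca, true, a->amax);
  mat Q = mlp_forward(a->critic, join_rows(S, A / a->amax), cc, false, 0.0);
  mat dOut = ones(Q.n_rows, 1) / (double)Q.n_rows;
  mat dX;
  mlp_backward(a->critic, cc, dOut, false, 0.0, &dX);
  mat dA = dX.cols(a->sdim, a->sdim + a->adim - 1) / a->amax;
  Grads g = mlp_backward(a->actor, ca, dA, true, a->amax);
  return grads_flatten(g);
}

// Critic evaluation at arbitrary state-action pairs.
// [[Rcpp::export]]
arma::vec cpp_agent_critic_value(SEXP ptr, const arma::mat& S, const arma::mat& A) {
  AgentPtr a(ptr);
  mat Q = mlp_forward_nograd(a->critic, join_rows(S, A / a->amax), false, 0.0);
  return Q.col(0);
}

// [[Rcpp::export]]
void cpp_agent_reset_noise(SEXP ptr) { AgentPtr(ptr)->noise.reset(); }

// [[Rcpp::export]]
void cpp_agent_set_exploration(SEXP ptr, double sigma, double eps_uniform) {
  AgentPtr a(ptr);
  a->noise.sigma = sigma;
  a->eps_uniform = eps_uniform;
}

// [[Rcpp::export]]
arma::vec cpp_agent_noise_state(SEXP ptr) { return AgentPtr(ptr)->noise.x; }

// [[Rcpp::export]]
Rcpp::List cpp_agent_dims(SEXP ptr) {
  AgentPtr a(ptr);
  return Rcpp::List::create(
      Rcpp::Named("sdim") = a->sdim, Rcpp::Named("adim") = a->adim,
      Rcpp::Named("h1") = a->actor.h1, Rcpp::Named("h2") = a->actor.h2,
      Rcpp::Named("amax") = a->amax, Rcpp::Named("gamma") = a->gamma,
      Rcpp::Named("tau") = a->tau, Rcpp::Named("lr") = a->lr,
      Rcpp::Named("capacity") = a->buf.capacity,
      Rcpp::Named("batch") = a->batch,
      Rcpp::Named("ou_theta") = a->noise.theta,
      Rcpp::Named("ou_sigma") = a->noise.sigma,
      Rcpp::Named("ou_dt") = a->noise.dt,
      Rcpp::Named("n_actor_params") = a->actor.n_params(),
      Rcpp::Named("n_critic_params") = a->critic.n_params());
}

// ----------------------- standalone replay buffer --------------------------
typedef Rcpp::XPtr<ReplayBuffer> RBPtr;

// [[Rcpp::export]]
SEXP cpp_rb_new(int capacity, int sdim, int adim) {
  ReplayBuffer* b = new ReplayBuffer();
  b->init(capacity, sdim, adim);
  return RBPtr(b, true);
}

// [[Rcpp::export]]
void cpp_rb_push(SEXP ptr, const arma::rowvec& s, const arma::rowvec& a,
                 double r, const arma::rowvec& s2, double done) {
  RBPtr b(ptr);
  if ((int)s.n_elem != b->sdim || (int)s2.n_elem != b->sdim)
    Rcpp::stop("state dimension mismatch");
  if ((int)a.n_elem != b->adim) Rcpp::stop("action dimension mismatch");
  b->push(s, a, r, s2, done);
}

// [[Rcpp::export]]
int cpp_rb_size(SEXP ptr) { return RBPtr(ptr)->size; }

// [[Rcpp::export]]
Rcpp::List cpp_rb_sample(SEXP ptr, int n) {
  RBPtr b(ptr);
  uvec idx = b->sample_idx(n);
  mat S, A, S2; vec R, D;
  b->gather(idx, S, A, R, S2, D);
  return Rcpp::List::create(
      Rcpp::Named("S") = S, Rcpp::Named("A") = A,
      Rcpp::Named("R") = Rcpp::NumericVector(R.begin(), R.end()),
      Rcpp::Named("S2") = S2,
      Rcpp::Named("D") = Rcpp::NumericVector(D.begin(), D.end()));
}

// Contents in FIFO order (oldest first); used by contract tests.
// [[Rcpp::export]]
Rcpp::List cpp_rb_contents(SEXP ptr) {
  RBPtr b(ptr);
  int n = b->size;
  uvec idx(n);
  int start = (b->size == b->capacity) ? b->pos : 0;
  for (int i = 0; i < n; ++i) idx(i) = (start + i) % b->capacity;
  mat S, A, S2; vec R, D;
  b->gather(idx, S, A, R, S2, D);
  return Rcpp::List::create(
      Rcpp::Named("S") = S, Rcpp::Named("A") = A,
      Rcpp::Named("R") = Rcpp::NumericVector(R.begin(), R.end()),
      Rcpp::Named("S2") = S2,
      Rcpp::Named("D") = Rcpp::NumericVector(D.begin(), D.end()));
}
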