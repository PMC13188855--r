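// Three-branch 1D CNN over one-hot encoded protein sequences.
//
// The input is a fixed L x C one-hot matrix (rows beyond the effective
// sequence length are all-zero padding).  Because the input is one-hot,
// each convolution window reduces to a sum of kernel rows indexed by the
// residue channels, so sequences are carried around as integer channel
// vectors rather than dense matrices.  1-max pooling makes the backward
// pass through the convolution sparse: per filter, gradient flows only
// into the argmax window.
//
// Windows that lie entirely in the padding region activate at ReLU(bias)
// for every filter; they are folded in analytically instead of being
// materialised, which keeps the forward pass exactly equal to a dense
// computation over the full L x C input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Branch {
  int l;            // kernel length (positions)
  // kernel weights held transposed, filters x (l * channels): the one-hot
  // input turns each convolution window into a gather-sum of columns, and
  // columns are contiguous in memory
  arma::mat W;
  arma::vec b;      // filters
  arma::mat gW, mW, vW;
  arma::vec gb, mb, vb;
};

struct FcLayer {
  arma::mat W;      // in x out
  arma::vec b;      // out
  arma::mat gW, mW, vW;
  arma::vec gb, mb, vb;
};

struct CnnModel {
  int input_length = 1000;
  int channels = 21;
  int filters = 128;
  int n_classes = 9;
  std::vector<Branch> branches;
  std::vector<FcLayer> fc;   // last layer -> n_classes, linear (sigmoid applied on top)
  long adam_t = 0;
};

// per-sequence record of where each pooled maximum came from
struct PoolTrace {
  // per branch: argmax window start (0-based) or -1 for a padding-only
  // window; and the pooled value itself (to gate the ReLU subgradient)
  std::vector<arma::ivec> argk;
  std::vector<arma::vec> beta;
};

static CnnModel* get_model(SEXP xp) {
  Rcpp::XPtr<CnnModel> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".cpp_cnn_create")]]
SEXP cpp_cnn_create(IntegerVector kernel_lengths, int filters,
                    IntegerVector fc_sizes, int n_classes,
                    int input_length, int channels) {
  CnnModel* m = new CnnModel();
  m->input_length = input_length;
  m->channels = channels;
  m->filters = filters;
  m->n_classes = n_classes;
  for (int i = 0; i < kernel_lengths.size(); ++i) {
    Branch br;
    br.l = kernel_lengths[i];
    if (br.l > input_length) {
      delete m;
      stop("kernel length %d exceeds input length %d", br.l, input_length);
    }
    int rows = br.l * channels;
    br.W = arma::zeros<arma::mat>(filters, rows);
    br.b = arma::zeros<arma::vec>(filters);
    br.gW = br.mW = br.vW = arma::zeros<arma::mat>(filters, rows);
    br.gb = br.mb = br.vb = arma::zeros<arma::vec>(filters);
    m->branches.push_back(br);
  }
  int in_dim = filters * (int)m->branches.size();
  std::vector<int> outs;
  for (int i = 0; i < fc_sizes.size(); ++i) outs.push_back(fc_sizes[i]);
  outs.push_back(n_classes);
  for (size_t i = 0; i < outs.size(); ++i) {
    FcLayer fl;
    fl.W = arma::zeros<arma::mat>(in_dim, outs[i]);
    fl.b = arma::zeros<arma::vec>(outs[i]);
    fl.gW = fl.mW = fl.vW = arma::zeros<arma::mat>(in_dim, outs[i]);
    fl.gb = fl.mb = fl.vb = arma::zeros<arma::vec>(outs[i]);
    m->fc.push_back(fl);
    in_dim = outs[i];
  }
  Rcpp::XPtr<CnnModel> ptr(m, true);
  return ptr;
}

// small uniform fan-in initialisation, U(-sqrt(1/fan_in), +sqrt(1/fan_in)).
// Deliberately smaller than ReLU-gain (He) scaling: with 1-max pooling the
// network generalises from shared motifs only in the small-initialisation
// feature-learning regime; larger scales push it into a lazy regime that
// memorises individual training sequences. Drawn from R's RNG so
// set.seed() upstream makes it reproducible.
// [[Rcpp::export(name = ".cpp_cnn_init")]]
void cpp_cnn_init(SEXP xp) {
  CnnModel* m = get_model(xp);
  for (auto& br : m->branches) {
    double s = std::sqrt(1.0 / (double)br.W.n_cols);   // fan-in = l * channels
    for (arma::uword j = 0; j < br.W.n_cols; ++j)
      for (arma::uword i = 0; i < br.W.n_rows; ++i)
        br.W(i, j) = (2.0 * R::unif_rand() - 1.0) * s;
    br.b.zeros();
  }
  for (auto& fl : m->fc) {
    double s = std::sqrt(1.0 / (double)fl.W.n_rows);
    for (arma::uword j = 0; j < fl.W.n_cols; ++j)
      for (arma::uword i = 0; i < fl.W.n_rows; ++i)
        fl.W(i, j) = (2.0 * R::unif_rand() - 1.0) * s;
    fl.b.zeros();
  }
  m->adam_t = 0;
}

// [[Rcpp::export(name = ".cpp_cnn_get_params")]]
List cpp_cnn_get_params(SEXP xp) {
  CnnModel* m = get_model(xp);
  List branches(m->branches.size());
  for (size_t i = 0; i < m->branches.size(); ++i)
    branches[i] = List::create(_["l"] = m->branches[i].l,
                               _["W"] = arma::mat(m->branches[i].W.t()),
                               _["b"] = m->branches[i].b);
  List fc(m->fc.size());
  for (size_t i = 0; i < m->fc.size(); ++i)
    fc[i] = List::create(_["W"] = m->fc[i].W, _["b"] = m->fc[i].b);
  return List::create(_["branches"] = branches, _["fc"] = fc);
}

// [[Rcpp::export(name = ".cpp_cnn_set_params")]]
void cpp_cnn_set_params(SEXP xp, List params) {
  CnnModel* m = get_model(xp);
  List branches = params["branches"];
  if ((size_t)branches.size() != m->branches.size())
    stop("branch count mismatch");
  for (size_t i = 0; i < m->branches.size(); ++i) {
    List bi = branches[i];
    arma::mat W = as<arma::mat>(bi["W"]);   // external layout (l*C) x F
    arma::vec b = as<arma::vec>(bi["b"]);
    if (W.n_rows != m->branches[i].W.n_cols || W.n_cols != m->branches[i].W.n_rows)
      stop("branch %d weight shape mismatch", (int)i + 1);
    m->branches[i].W = W.t();
    m->branches[i].b = b;
  }
  List fc = params["fc"];
  if ((size_t)fc.size() != m->fc.size()) stop("fc layer count mismatch");
  for (size_t i = 0; i < m->fc.size(); ++i) {
    List fi = fc[i];
    arma::mat W = as<arma::mat>(fi["W"]);
    arma::vec b = as<arma::vec>(fi["b"]);
    if (W.n_rows != m->fc[i].W.n_rows || W.n_cols != m->fc[i].W.n_cols)
      stop("fc layer %d weight shape mismatch", (int)i + 1);
    m->fc[i].W = W;
    m->fc[i].b = b;
  }
}

// convolution + ReLU + 1-max pooling for one sequence; fills `pooled`
// (concatenated across branches) and the pooling trace
static void conv_pool(const CnnModel* m, const arma::ivec& seq, int leff,
                      arma::vec& pooled, PoolTrace& tr) {
  int nb = (int)m->branches.size();
  int F = m->filters, C = m->channels;
  pooled.set_size(F * nb);
  tr.argk.resize(nb);
  tr.beta.resize(nb);
  for (int bi = 0; bi < nb; ++bi) {
    const Branch& br = m->branches[bi];
    int l = br.l;
    int mapLen = m->input_length - l + 1;
    int kmax = std::min(leff, mapLen);   // windows touching sequence content
    arma::vec best(F);
    arma::ivec argk(F);
    if (kmax < mapLen) {
      // padding-only windows all activate at ReLU(bias)
      best = arma::clamp(br.b, 0.0, arma::datum::inf);
      argk.fill(-1);
    } else {
      best.fill(-arma::datum::inf);
      argk.fill(0);
    }
    arma::vec z(F);
    for (int k = 0; k < kmax; ++k) {
      z = br.b;
      int jmax = std::min(l, leff - k);  // rows beyond leff are zero
      for (int j = 0; j < jmax; ++j)
        z += br.W.col((arma::uword)(j * C + seq[k + j]));
      for (int f = 0; f < F; ++f) {
        double phi = z[f] > 0.0 ? z[f] : 0.0;
        if (phi > best[f]) { best[f] = phi; argk[f] = k; }
      }
    }
    for (int f = 0; f < F; ++f) pooled[bi * F + f] = best[f];
    tr.argk[bi] = argk;
    tr.beta[bi] = best;
  }
}

// route pooled-gradient g (length F*nb) back into conv weight/bias grads
static void conv_backward(CnnModel* m, const arma::ivec& seq, int leff,
                          const PoolTrace& tr, const arma::vec& g) {
  int nb = (int)m->branches.size();
  int F = m->filters, C = m->channels;
  for (int bi = 0; bi < nb; ++bi) {
    Branch& br = m->branches[bi];
    int l = br.l;
    for (int f = 0; f < F; ++f) {
      double gf = g[bi * F + f];
      if (gf == 0.0) continue;
      if (tr.beta[bi][f] <= 0.0) continue;     // ReLU gate closed
      int k = tr.argk[bi][f];
      br.gb[f] += gf;
      if (k >= 0) {
        int jmax = std::min(l, leff - k);
        for (int j = 0; j < jmax; ++j)
          br.gW((arma::uword)f, (arma::uword)(j * C + seq[k + j])) += gf;
      }
      // padding-window maximum (k == -1): only the bias participates
    }
  }
}

static void zero_grads(CnnModel* m) {
  for (auto& br : m->branches) { br.gW.zeros(); br.gb.zeros(); }
  for (auto& fl : m->fc) { fl.gW.zeros(); fl.gb.zeros(); }
}

static void adam_step(CnnModel* m, double lr, double beta1, double beta2,
                      double eps) {
  m->adam_t += 1;
  double c1 = 1.0 - std::pow(beta1, (double)m->adam_t);
  double c2 = 1.0 - std::pow(beta2, (double)m->adam_t);
  auto upd_mat = [&](arma::mat& W, arma::mat& g, arma::mat& mm, arma::mat& vv) {
    mm = beta1 * mm + (1.0 - beta1) * g;
    vv = beta2 * vv + (1.0 - beta2) * (g % g);
    W -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  };
  auto upd_vec = [&](arma::vec& b, arma::vec& g, arma::vec& mm, arma::vec& vv) {
    mm = beta1 * mm + (1.0 - beta1) * g;
    vv = beta2 * vv + (1.0 - beta2) * (g % g);
    b -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  };
  for (auto& br : m->branches) {
    upd_mat(br.W, br.gW, br.mW, br.vW);
    upd_vec(br.b, br.gb, br.mb, br.vb);
  }
  for (auto& fl : m->fc) {
    upd_mat(fl.W, fl.gW, fl.mW, fl.vW);
    upd_vec(fl.b, fl.gb, fl.mb, fl.vb);
  }
}

// fully-connected forward for a batch; returns probabilities, stores
// pre-activations and (dropped-out) hidden activations for backprop
struct FcTrace {
  std::vector<arma::mat> Z;      // pre-activations per layer (B x out)
  std::vector<arma::mat> Hdrop;  // post-ReLU post-dropout inputs to next layer
  arma::mat logits;
  arma::mat probs;
};

static void fc_forward(const CnnModel* m, const arma::mat& H0,
                       bool training, double dropout, FcTrace& tr) {
  size_t L = m->fc.size();
  tr.Z.resize(L);
  tr.Hdrop.resize(L);          // Hdrop[i] = input to layer i+1 (after dropout)
  arma::mat H = H0;
  for (size_t i = 0; i < L; ++i) {
    const FcLayer& fl = m->fc[i];
    arma::mat Z = H * fl.W;
    Z.each_row() += fl.b.t();
    tr.Z[i] = Z;
    if (i + 1 < L) {
      arma::mat A = arma::clamp(Z, 0.0, arma::datum::inf);
      if (training && dropout > 0.0) {
        double keep = 1.0 - dropout;
        arma::mat mask(A.n_rows, A.n_cols);
        for (arma::uword r = 0; r < A.n_rows; ++r)
          for (arma::uword c = 0; c < A.n_cols; ++c)
            mask(r, c) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
        A %= mask;
      }
      tr.Hdrop[i] = A;
      H = A;
    } else {
      tr.logits = Z;
      tr.probs = 1.0 / (1.0 + arma::exp(-Z));
    }
  }
}

static arma::ivec as_seq(SEXP s) { return as<arma::ivec>(s); }

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
arma::mat cpp_cnn_predict(SEXP xp, List seqs, IntegerVector leff,
                          bool training = false, double dropout = 0.0) {
  CnnModel* m = get_model(xp);
  int n = seqs.size();
  int nb = (int)m->branches.size();
  arma::mat H0(n, m->filters * nb);
  PoolTrace tr;
  arma::vec pooled;
  for (int i = 0; i < n; ++i) {
    arma::ivec s = as_seq(seqs[i]);
    conv_pool(m, s, leff[i], pooled, tr);
    H0.row(i) = pooled.t();
  }
  FcTrace ft;
  fc_forward(m, H0, training, dropout, ft);
  return ft.probs;
}

// [[Rcpp::export(name = ".cpp_cnn_logits")]]
arma::mat cpp_cnn_logits(SEXP xp, List seqs, IntegerVector leff) {
  CnnModel* m = get_model(xp);
  int n = seqs.size();
  int nb = (int)m->branches.size();
  arma::mat H0(n, m->filters * nb);
  PoolTrace tr;
  arma::vec pooled;
  for (int i = 0; i < n; ++i) {
    arma::ivec s = as_seq(seqs[i]);
    conv_pool(m, s, leff[i], pooled, tr);
    H0.row(i) = pooled.t();
  }
  FcTrace ft;
  fc_forward(m, H0, false, 0.0, ft);
  return ft.logits;
}

// one pass over the training data in the given order; returns mean
// binary cross-entropy over all sequence-class pairs seen
// [[Rcpp::export(name = ".cpp_cnn_train_epoch")]]
double cpp_cnn_train_epoch(SEXP xp, List seqs, IntegerVector leff,
                           arma::mat Y, IntegerVector order,
                           int batch_size, double lr, double dropout,
                           double beta1 = 0.9, double beta2 = 0.999,
                           double eps = 1e-8) {
  CnnModel* m = get_model(xp);
  int n = order.size();
  int nb = (int)m->branches.size();
  int C = m->n_classes;
  size_t L = m->fc.size();
  double loss_sum = 0.0;
  long loss_n = 0;
  const double clip = 1e-12;

  for (int start = 0; start < n; start += batch_size) {
    int B = std::min(batch_size, n - start);
    arma::mat H0(B, m->filters * nb);
    std::vector<PoolTrace> traces(B);
    std::vector<arma::ivec> bseqs(B);
    arma::ivec bleff(B);
    arma::mat Yb(B, C);
    arma::vec pooled;
    for (int i = 0; i < B; ++i) {
      int idx = order[start + i];
      bseqs[i] = as_seq(seqs[idx]);
      bleff[i] = leff[idx];
      conv_pool(m, bseqs[i], bleff[i], pooled, traces[i]);
      H0.row(i) = pooled.t();
      Yb.row(i) = Y.row(idx);
    }
    FcTrace ft;
    fc_forward(m, H0, true, dropout, ft);

    arma::mat P = arma::clamp(ft.probs, clip, 1.0 - clip);
    loss_sum += arma::accu(-(Yb % arma::log(P) + (1.0 - Yb) % arma::log(1.0 - P)));
    loss_n += (long)B * C;

    zero_grads(m);
    // d loss / d logits for mean-over-(B*C) BCE with sigmoid output
    arma::mat G = (ft.probs - Yb) / ((double)B * C);
    // backward through FC stack
    for (int i = (int)L - 1; i >= 0; --i) {
      FcLayer& fl = m->fc[i];
      const arma::mat& Hin = (i == 0) ? H0 : ft.Hdrop[i - 1];
      fl.gW = Hin.t() * G;
      fl.gb = arma::sum(G, 0).t();
      arma::mat Gh = G * fl.W.t();
      if (i > 0) {
        // undo dropout scaling and gate by ReLU: Hdrop[i-1] already embeds
        // both; its nonzero pattern is exactly where gradient may flow, and
        // the inverse-keep scaling applies to the gradient as well
        arma::mat gate = arma::conv_to<arma::mat>::from(ft.Hdrop[i - 1] != 0.0);
        double keep = 1.0 - dropout;
        if (dropout > 0.0) gate /= keep;
        // additionally require pre-activation > 0 (ReLU subgradient)
        gate %= arma::conv_to<arma::mat>::from(ft.Z[i - 1] > 0.0);
        G = Gh % gate;
      } else {
        // gradient wrt pooled features -> route into conv branches
        for (int r = 0; r < B; ++r)
          conv_backward(m, bseqs[r], bleff[r], traces[r], Gh.row(r).t());
      }
    }
    adam_step(m, lr, beta1, beta2, eps);
  }
  return loss_n > 0 ? loss_sum / (double)loss_n : 0.0;
}

// exact gradient of the mean BCE over one batch (dropout off), in the
// same shape as the parameter list; used by gradient-checking tests
// [[Rcpp::export(name = ".cpp_cnn_grads")]]
List cpp_cnn_grads(SEXP xp, List seqs, IntegerVector leff, arma::mat Y) {
  CnnModel* m = get_model(xp);
  int B = seqs.size();
  int C = m->n_classes;
  int nb = (int)m->branches.size();
  size_t L = m->fc.size();
  arma::mat H0(B, m->filters * nb);
  std::vector<PoolTrace> traces(B);
  std::vector<arma::ivec> bseqs(B);
  arma::vec pooled;
  for (int i = 0; i < B; ++i) {
    bseqs[i] = as_seq(seqs[i]);
    conv_pool(m, bseqs[i], leff[i], pooled, traces[i]);
    H0.row(i) = pooled.t();
  }
  FcTrace ft;
  fc_forward(m, H0, false, 0.0, ft);
  zero_grads(m);
  arma::mat G = (ft.probs - Y) / ((double)B * C);
  for (int i = (int)L - 1; i >= 0; --i) {
    FcLayer& fl = m->fc[i];
    const arma::mat& Hin = (i == 0) ? H0 : ft.Hdrop[i - 1];
    fl.gW = Hin.t() * G;
    fl.gb = arma::sum(G, 0).t();
    arma::mat Gh = G * fl.W.t();
    if (i > 0) {
      arma::mat gate = arma::conv_to<arma::mat>::from(ft.Z[i - 1] > 0.0);
      G = Gh % gate;
    } else {
      for (int r = 0; r < B; ++r)
        conv_backward(m, bseqs[r], leff[r], traces[r], Gh.row(r).t());
    }
  }
  List branches(nb);
  for (int i = 0; i < nb; ++i)
    branches[i] = List::create(_["l"] = m->branches[i].l,
                               _["W"] = arma::mat(m->branches[i].gW.t()),
                               _["b"] = m->branches[i].gb);
  List fc(L);
  for (size_t i = 0; i < L; ++i)
    fc[i] = List::create(_["W"] = m->fc[i].gW, _["b"] = m->fc[i].gb);
  return List::create(_["branches"] = branches, _["fc"] = fc);
}

// full activation maps, pooled values, logits and probabilities for a
// single sequence (inference mode) — the interpreter's raw material
// [[Rcpp::export(name = ".cpp_cnn_detail")]]
List cpp_cnn_detail(SEXP xp, IntegerVector seq, int leff) {
  CnnModel* m = get_model(xp);
  arma::ivec s = as<arma::ivec>(seq);
  int nb = (int)m->branches.size();
  int F = m->filters, C = m->channels;
  List phi_list(nb), beta_list(nb);
  IntegerVector klens(nb);
  arma::vec pooled(F * nb);
  for (int bi = 0; bi < nb; ++bi) {
    const Branch& br = m->branches[bi];
    int l = br.l;
    int mapLen = m->input_length - l + 1;
    int kmax = std::min(leff, mapLen);
    arma::mat phi(mapLen, F);
    arma::rowvec pad = arma::clamp(br.b, 0.0, arma::datum::inf).t();
    for (int k = kmax; k < mapLen; ++k) phi.row(k) = pad;
    arma::vec z(F);
    for (int k = 0; k < kmax; ++k) {
      z = br.b;
      int jmax = std::min(l, leff - k);
      for (int j = 0; j < jmax; ++j)
        z += br.W.col((arma::uword)(j * C + s[k + j]));
      phi.row(k) = arma::clamp(z, 0.0, arma::datum::inf).t();
    }
    arma::vec beta = arma::max(phi, 0).t();
    for (int f = 0; f < F; ++f) pooled[bi * F + f] = beta[f];
    phi_list[bi] = phi;
    beta_list[bi] = beta;
    klens[bi] = l;
  }
  FcTrace ft;
  arma::mat H0 = pooled.t();
  fc_forward(m, H0, false, 0.0, ft);
  return List::create(_["kernel_lengths"] = klens,
                      _["phi"] = phi_list,
                      _["beta"] = beta_list,
                      _["pooled"] = pooled,
                      _["logits"] = ft.logits.row(0).t(),
                      _["probs"] = ft.probs.row(0).t());
}

// gradient of the pre-sigmoid class logit w.r.t. every pooled value
// (exact backprop through the FC head, inference mode)
// [[Rcpp::export(name = ".cpp_cnn_alpha")]]
arma::vec cpp_cnn_alpha(SEXP xp, IntegerVector seq, int leff, int class0) {
  CnnModel* m = get_model(xp);
  if (class0 < 0 || class0 >= m->n_classes) stop("class index out of range");
  arma::ivec s = as<arma::ivec>(seq);
  int nb = (int)m->branches.size();
  arma::vec pooled;
  PoolTrace tr;
  conv_pool(m, s, leff, pooled, tr);
  FcTrace ft;
  arma::mat H0 = pooled.t();
  fc_forward(m, H0, false, 0.0, ft);
  size_t L = m->fc.size();
  arma::vec g = m->fc[L - 1].W.col(class0);
  for (int i = (int)L - 2; i >= 0; --i) {
    arma::vec gate = arma::conv_to<arma::vec>::from(ft.Z[i].row(0).t() > 0.0);
    g %= gate;
    g = m->fc[i].W * g;
  }
  return g;  // length filters * n_branches, branch-major like pooled
}
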