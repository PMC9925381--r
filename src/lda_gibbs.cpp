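#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the hierarchical multinomial (LDA) model of
// region x cell count matrices. Cells play the role of documents and
// regions of words; counts are expanded to token instances. Uses R's RNG
// so fits are reproducible under set.seed(). The point estimate averages
// theta and phi over the final sweeps.

// [[Rcpp::export]]
List lda_gibbs(IntegerVector doc, IntegerVector word, int n_doc, int n_word,
               int K, double alpha, double beta, int n_iter, int n_avg) {
  const int n_tok = doc.size();
  if (n_avg > n_iter) n_avg = n_iter;

  std::vector<int> z(n_tok);
  std::vector<double> ndk((size_t)n_doc * K, 0.0);
  std::vector<double> nkw((size_t)K * n_word, 0.0);
  std::vector<double> nk(K, 0.0);

  // random initial assignment
  for (int t = 0; t < n_tok; ++t) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[t] = k;
    ndk[(size_t)doc[t] * K + k] += 1.0;
    nkw[(size_t)k * n_word + word[t]] += 1.0;
    nk[k] += 1.0;
  }

  std::vector<double> prob(K);
  std::vector<double> theta_acc((size_t)n_doc * K, 0.0);
  std::vector<double> phi_acc((size_t)K * n_word, 0.0);
  NumericVector loglik(n_iter);
  const double Vbeta = n_word * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < n_tok; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      ndk[(size_t)d * K + k] -= 1.0;
      nkw[(size_t)k * n_word + w] -= 1.0;
      nk[k] -= 1.0;

      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        double p = (ndk[(size_t)d * K + j] + alpha) *
                   (nkw[(size_t)j * n_word + w] + beta) / (nk[j] + Vbeta);
        prob[j] = p;
        tot += p;
      }
      double u = unif_rand() * tot;
      double cum = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += prob[j];
        if (u <= cum) { k = j; break; }
      }
      z[t] = k;
      ndk[(size_t)d * K + k] += 1.0;
      nkw[(size_t)k * n_word + w] += 1.0;
      nk[k] += 1.0;
    }

    // collapsed log joint p(w, z) up to constants, as a convergence trace
    double ll = 0.0;
    for (int j = 0; j < K; ++j) {
      for (int w = 0; w < n_word; ++w)
        ll += R::lgammafn(nkw[(size_t)j * n_word + w] + beta);
      ll -= R::lgammafn(nk[j] + Vbeta);
    }
    for (int d = 0; d < n_doc; ++d)
      for (int j = 0; j < K; ++j)
        ll += R::lgammafn(ndk[(size_t)d * K + j] + alpha);
    loglik[it] = ll;

    if (it >= n_iter - n_avg) {
      for (int d = 0; d < n_doc; ++d) {
        double nd = 0.0;
        for (int j = 0; j < K; ++j) nd += ndk[(size_t)d * K + j];
        for (int j = 0; j < K; ++j)
          theta_acc[(size_t)d * K + j] +=
            (ndk[(size_t)d * K + j] + alpha) / (nd + K * alpha);
      }
      for (int j = 0; j < K; ++j)
        for (int w = 0; w < n_word; ++w)
          phi_acc[(size_t)j * n_word + w] +=
            (nkw[(size_t)j * n_word + w] + beta) / (nk[j] + Vbeta);
    }
  }

  NumericMatrix theta(n_doc, K), phi(K, n_word);
  for (int d = 0; d < n_doc; ++d)
    for (int j = 0; j < K; ++j)
      theta(d, j) = theta_acc[(size_t)d * K + j] / n_avg;
  for (int j = 0; j < K; ++j)
    for (int w = 0; w < n_word; ++w)
      phi(j, w) = phi_acc[(size_t)j * n_word + w] / n_avg;

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["loglik"] = loglik);
}
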