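# Build a minimal benchmark tibble from parallel vectors. One predictor
# column ("m1" by default) is enough for most evaluation tests.
make_bench <- function(exp_ddg, pred, censored = FALSE, method = "m1",
                       exp_sigma = 0, tki = "tki1") {
  n <- length(exp_ddg)
  out <- tibble::tibble(
    tki = rep_len(tki, n),
    mutation = sprintf("A%dV", seq_len(n) + 100L),
    exp_ddg = exp_ddg,
    exp_sigma = rep_len(exp_sigma, n),
    censored = rep_len(censored, n)
  )
  out[[paste0(method, "_ddg")]] <- pred
  out[[paste0(method, "_sigma")]] <- 0
  out
}

# Pairwise (Mann-Whitney) AUC with ties counted one half: the brute-force
# oracle for the stepped-sweep trapezoidal AUC.
pairwise_auc <- function(pos, neg) {
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  mean(gt + 0.5 * eq)
}
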