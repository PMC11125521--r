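# shared fixtures: one moderate parameter set per model
tm_ref <- function() telegraph_params(1, 1, 10, 1)
tsm_ref <- function() complex_model_params("TSM", rho = 15, lam1 = 2, lam2 = 2, gam = 1)
cpm_ref <- function() complex_model_params("CPM", rho = 15, lam1 = 0.2, lam2 = 2,
                                           gam = 1, q1 = 0.5)
pfm_ref <- function() complex_model_params("PFM", rho = 10, lam = 1, gam = 1, mu = 0.1)
nfm_ref <- function() complex_model_params("NFM", rho = 10, lam = 1, gam = 1, nu = 0.1)

pmf_mean <- function(p) sum((seq_along(p) - 1) * p)

# random pmf on 0..(k-1)
rand_pmf <- function(k) {
  x <- rexp(k)
  x / sum(x)
}
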