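# Parameter sets used across tests: the single-cursor fits reported for each
# experiment / response type, plus the matching MLE fit.
exp1_learning_dn <- function() dn_params(w = 5.3271e-4, k = 7.7806e-7)
exp1_feedback_dn <- function() dn_params(w = 4.0541e-4, k = 9.2642e-5)
exp2_learning_dn <- function() dn_params(w = 2.0002e-4, k = 2.1434e-6)
exp3_learning_dn <- function() dn_params(w = 4.7525e-4, k = 2.1102e-6)
exp1_learning_mle <- function() mle_params(gain = 2.963e5, ratio_sv = 122.2,
                                           ratio_kv = 8.055)

exp1_error_grid <- function() c(0, 7.5, 15, 30, 45)

relerr <- function(est, true) abs(est - true) / abs(true)
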