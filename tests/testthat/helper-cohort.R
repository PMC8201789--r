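# Directly simulated long table: participant intercepts + family offsets,
# the structure the mixed model assumes (no fitting step involved).
simulate_long_table <- function(n = 16, offsets = c(two_param = 0,
                                                    three_param = -0.27,
                                                    three_param_exp = 0.16),
                                participant_sd = 0.4, resid_sd = 0.05,
                                mu = 4.4) {
  ids <- sprintf("p%02d", seq_len(n))
  u <- rnorm(n, 0, participant_sd)
  grid <- expand.grid(participant_id = ids,
                      family = names(offsets),
                      formulation = cs_formulations(),
                      stringsAsFactors = FALSE)
  grid$outcome <- "cs"
  grid$value <- mu + u[match(grid$participant_id, ids)] +
    offsets[grid$family] + rnorm(nrow(grid), 0, resid_sd)
  grid
}
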