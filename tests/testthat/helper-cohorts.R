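# shared fixture builders; everything is generated in code at test time

study2_designs <- function(seed = 3) {
  list(everyday = build_trial_templates(build_frequency_table("everyday"),
                                        2L, seed = seed),
       uniform = build_trial_templates(build_frequency_table("uniform"),
                                       22L, seed = seed + 1L),
       reversed_everyday = build_trial_templates(
         build_frequency_table("reversed_everyday"), 2L, seed = seed + 2L))
}

# three frequency-condition cohorts with disambiguated participant ids
simulate_study2_cohorts <- function(coupling, seed, n_participants = 20,
                                    conditions = c("everyday", "uniform",
                                                   "reversed_everyday"),
                                    ddm = ddm_params()) {
  designs <- study2_designs()
  out <- lapply(seq_along(conditions), function(i) {
    cnd <- conditions[i]
    tr <- simulate_ans_cohort(designs[[cnd]],
                              cohort_spec(n_participants, 0.1, seed + i),
                              ddm, coupling)
    tr$participant_id <- paste0(substr(cnd, 1, 3), "_", tr$participant_id)
    tr
  })
  do.call(rbind, out)
}

study2_freq_tables <- function() {
  list(everyday = build_frequency_table("everyday"),
       uniform = build_frequency_table("uniform"),
       reversed_everyday = build_frequency_table("reversed_everyday"))
}

# tiny hand-checkable trial table
toy_trials <- function() {
  data.frame(participant_id = "p1", condition = "study1", block = 1L,
             trial_index = 1:4, left_value = c(5, 10, 5, 10),
             right_value = c(10, 5, 10, 5),
             response_side = c("right", "left", "left", "left"),
             correct = c(TRUE, TRUE, FALSE, TRUE),
             rt_ms = c(400, 500, 900, 450))
}
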