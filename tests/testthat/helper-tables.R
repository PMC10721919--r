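# A small synthetic feature table with controllable signal, built without any
# mesh machinery, so the ML stage can be tested in isolation.
make_feature_table <- function(n_per_class = 40, classes = c("fungiform",
                                                             "filiform",
                                                             "none"),
                               n_participants = 4, signal = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    type <- rep(classes, each = n_per_class)
    participant <- sample(sprintf("P%02d", seq_len(n_participants)), n,
                          replace = TRUE)
    gender <- ifelse(as.integer(sub("P", "", participant)) %% 2 == 0, "F", "M")
    age <- ifelse(gender == "F", 26, 33)
    tab <- tibble::tibble(
      segment = seq_len(n), type = type, participant = participant,
      gender = gender, age = age,
      age_group = ifelse(age <= 28, "young", "old"))
    for (f in feature_families()$feature) {
      tab[[f]] <- rnorm(n) + signal * as.integer(factor(type)) *
        (match(f, feature_families()$feature) %% 3 == 0)
    }
    tab
  })
}
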