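## Shared fixtures: everything is generated in code at test time.

SUBSCALES <- maceforest:::MACE_SUBSCALES

## flat per-age prevalence curve; `p` recycled over the 10 subscales
flat_curve <- function(p) {
  matrix(p, nrow = 10, ncol = 18,
         dimnames = list(SUBSCALES, paste0("age_", 1:18)))
}

## long exposure data frame for a set of subjects from 10 x 18 score
## matrices (default all zero); `cells` is a list of lists
## (subject, subscale, age, score)
make_exposures <- function(n_subjects = 1, cells = list()) {
  out <- expand.grid(subject_id = seq_len(n_subjects),
                     subscale = SUBSCALES, age = 1:18,
                     stringsAsFactors = FALSE)
  out$score <- 0
  for (c in cells) {
    i <- out$subject_id == c$subject & out$subscale == c$subscale & out$age == c$age
    out$score[i] <- c$score
  }
  class(out) <- c("mace_exposures", "data.frame")
  out
}

## small fast forest configuration for unit tests
fast_config <- function(...) {
  args <- list(...)
  defaults <- list(n_trees = 25, n_split_reps = 2,
                   split_criterion = "variance", seed = 42L)
  do.call(forest_config, utils::modifyList(defaults, args))
}

## gaussian predictor matrix with names
gauss_x <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  x
}
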