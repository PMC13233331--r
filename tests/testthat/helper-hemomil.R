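# Shared fixtures, all built in code.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(embedding_dim = 6L, bag_size = 50L, latent_dim = 8L,
         n_heads = 2L, n_layers = 2L, n_classes = 8L,
         hb_loss_weight = 0.5, dropout = 0, seed = 7L),
    list(...))
  do.call(mil_config, args)
}

# uniform class priors so every class is populated even at small n
tiny_cohort <- function(n_patients = 24L, n_cells = 30L, embedding_dim = 6L,
                        separation = 5, seed = 3L) {
  generate_cohort(n_patients, class_priors = rep(1 / 8, 8L),
                  n_cells = n_cells, seed = seed,
                  embedding_dim = embedding_dim, separation = separation)
}

random_simplex <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# random probability matrix over the hierarchy's coarse classes
random_prob_matrix <- function(n, h) {
  P <- t(vapply(seq_len(n), function(i) random_simplex(8L), numeric(8L)))
  colnames(P) <- h$coarse_classes
  P
}

# The positive-control study: a 5-fold ensemble trained on 400 patients
# (200 cells per bag, embedding dimension 32, 6 cell types, separation 5)
# and evaluated on a fresh 200-patient cohort from the same conditions.
# Trained once per test session and shared (training is the expensive step).
.pc_cache <- new.env(parent = emptyenv())

positive_control <- function() {
  if (!is.null(.pc_cache$fit)) return(as.list(.pc_cache))
  cohort <- generate_cohort(400L, n_cells = 200L, seed = 11L,
                            embedding_dim = 32L, separation = 5)
  cfg <- mil_config(embedding_dim = 32L, bag_size = 500L, latent_dim = 80L,
                    n_heads = 4L, n_layers = 2L, n_classes = 8L,
                    hb_loss_weight = 1.0, dropout = 0.1, seed = 1L)
  fit <- hemomil(cohort$manifest, cohort$bags, cfg, k = 5L,
                 params = train_params(epochs = 60L, lr = 2e-3,
                                       batch_size = 8L, patience = 8L,
                                       lr_patience = 3L, bag_size = 80L,
                                       class_balance = TRUE),
                 seed = 21L)
  recipes <- default_recipes(6L, embedding_dim = 32L, separation = 5,
                             seed = hemomil:::derive_seed(11L, 0L))
  test <- generate_cohort(300L, n_cells = 200L, seed = 1211L,
                          embedding_dim = 32L, separation = 5,
                          recipes = recipes)
  .pc_cache$cohort <- cohort
  .pc_cache$fit <- fit
  .pc_cache$test <- test
  as.list(.pc_cache)
}
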