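# Shared in-code fixtures. Small dimensions keep individual tests fast; the
# acceptance tests use the generator defaults where the check is about the
# documented study conditions.

# a tiny hand-written dataset with known degrees
tiny_interactions <- function() {
  Y <- matrix(0, 6, 4, dimnames = list(paste0("d", 1:6), paste0("t", 1:4)))
  Y[c(1, 2, 3, 4, 5), 1] <- 1   # t1: degree 5
  Y[c(1, 2, 6), 2] <- 1         # t2: degree 3
  Y[4, 3] <- 1                  # t3: degree 1
  Y[5, 4] <- 1                  # t4: degree 1
  interaction_matrix(Y)
}

# small generated dataset for pipeline-level tests
small_config <- function(seed = 1L, ...) {
  generator_config(u = 30L, v = 12L, p = 64L, q = 16L, density = 0.12,
                   skew = 1, signal = 0.1, noise = 0, seed = seed, ...)
}

similarity_from <- function(m, ids) similarity_matrix(m, ids = ids)

expect_no_na <- function(x) expect_false(anyNA(x))
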