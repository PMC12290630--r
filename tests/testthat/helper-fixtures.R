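# worked-example data: occasion B is a scaled copy of occasion A, so the
# product-moment correlation is perfect but consistency is not
worked_matrix <- function() {
  cbind(A = c(1, 3, 6, 9, 12), B = c(3, 9, 18, 27, 36))
}

# independent mean-square oracle via base aov()
aov_mean_squares <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    occasion = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ subject + occasion, data = d))[[1]]
  list(msbs = tab["subject", "Mean Sq"],
       msbm = tab["occasion", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

random_matrix <- function(n = 8, k = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * k, mean = 1), nrow = n)
}

# volume set with i.i.d. normal voxels
random_volume_set <- function(n = 8, k = 2, dims = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  occ <- lapply(seq_len(k), function(j) {
    lapply(seq_len(n), function(i) array(rnorm(prod(dims)), dim = dims))
  })
  volume_set(occ)
}

full_mask <- function(dims = c(4, 4, 4)) brain_mask(array(1, dims))

# extract one voxel's n x k measurement matrix from a volume set
voxel_matrix <- function(vs, voxel) {
  k <- length(vs$occasions)
  n <- dim(vs$occasions[[1]])[4]
  sapply(seq_len(k), function(j) {
    sapply(seq_len(n), function(i) {
      as.vector(vs$occasions[[j]][, , , i])[voxel]
    })
  })
}

# random matrix with genuine between-subject signal (positive expected ICC)
random_icc_matrix <- function(n = 10, k = 2, seed = NULL, s2b = 2, s2w = 1) {
  if (!is.null(seed)) set.seed(seed)
  sweep(matrix(rnorm(n * k, sd = sqrt(s2w)), nrow = n), 1L,
        rnorm(n, sd = sqrt(s2b)), `+`)
}
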