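# shared fixtures: all test data is generated in code, no files

make_gaussian_df <- function(n, seed = 1, sd = 1.5) {
  set.seed(seed)
  df <- data.frame(age = runif(n, 18, 90),
                   sex = sample(c("F", "M"), n, replace = TRUE))
  df$y <- 22 + 4 * exp(-((df$age - 50) / 20)^2) + 0.5 * (df$sex == "M") +
    rnorm(n, 0, sd)
  df
}

# split a data frame into m random site chunks (every chunk nonempty)
partition_sites <- function(df, m, seed = 1, outcome = "y") {
  set.seed(seed)
  idx <- sample(rep(seq_len(m), length.out = nrow(df)))
  lapply(seq_len(m), function(j) {
    site_data(df[idx == j, , drop = FALSE], outcome, sprintf("s%02d", j))
  })
}

rbind_sites <- function(sites) {
  do.call(rbind, lapply(sites, function(s) s$data))
}

# independently coded Cox-de Boor recursion (oracle for basis evaluation)
cox_de_boor <- function(knots, x, degree) {
  m <- length(knots) - degree - 1L
  B <- matrix(0, length(x), length(knots) - 1L)
  for (j in seq_len(ncol(B))) {
    B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
  }
  # right-closure at the final interval
  last <- max(which(knots < max(knots)))
  B[x == max(knots), last] <- 1
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(x), length(knots) - d - 1L)
    for (j in seq_len(ncol(Bn))) {
      d1 <- knots[j + d] - knots[j]
      d2 <- knots[j + d + 1] - knots[j + 1]
      t1 <- if (d1 > 0) (x - knots[j]) / d1 * B[, j] else 0
      t2 <- if (d2 > 0) (knots[j + d + 1] - x) / d2 * B[, j + 1] else 0
      Bn[, j] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(m), drop = FALSE]
}

# draw a valid random y vector inside the family support
draw_valid_y <- function(family, theta, n = 20, seed = 1) {
  set.seed(seed)
  family_quantile(family, runif(n, 0.03, 0.97), theta)
}
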