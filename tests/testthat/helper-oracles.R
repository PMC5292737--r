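# Shared oracles and fixture loaders for the test suite.

bacillus_inputs <- function() {
  f <- bacillus_files()
  list(dm = read_table1_fixture(f$distances),
       host = read_host_tree(f$host_tree),
       mapping = read.csv(f$mapping, stringsAsFactors = FALSE))
}

default_calibrations <- function() {
  data.frame(tip_a = c("R2Brfun", "R2BggA"), tip_b = c("R2Brdeg", "R2Ba"),
             age_myr = c(5.4, 15.4))
}

# expected p-distance under Jukes-Cantor after total path time t2 (both
# lineages combined) at substitution rate r
jc_expected_p <- function(r, t2) 0.75 * (1 - exp(-(4 / 3) * r * t2))

# first-principles simple linear regression from sums of squares
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r = r, r2 = r^2)
}

# brute-force four-point oracle: for four taxa the generating unrooted
# topology is the pairing whose between-pair distance sum is smallest
four_point_split <- function(d, labs) {
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sums <- vapply(pairings, function(p) d[labs[p[1]], labs[p[2]]] +
                   d[labs[p[3]], labs[p[4]]], 0)
  p <- pairings[[which.min(sums)]]
  list(side_a = labs[p[1:2]], side_b = labs[p[3:4]])
}

# does an unrooted tree contain the bipartition side | rest?
has_split <- function(phy, side) {
  phy <- ape::unroot(phy)
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  for (k in seq_along(parts)[-1]) {
    cl <- labs[parts[[k]]]
    if (setequal(cl, side) || setequal(setdiff(labs, cl), side)) return(TRUE)
  }
  FALSE
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
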