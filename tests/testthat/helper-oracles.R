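# Independent oracles used by the tests. These are deliberately naive
# (flat loops, exhaustive search) and share no code with the package paths
# they check.

naive_moments <- function(v) {
  n <- length(v)
  s <- 0
  for (x in v) s <- s + x
  m <- s / n
  s2 <- 0; s3 <- 0; mn <- v[1]; mx <- v[1]
  for (x in v) {
    d <- x - m
    s2 <- s2 + d^2
    s3 <- s3 + d^3
    if (x < mn) mn <- x
    if (x > mx) mx <- x
  }
  list(mean = m, rmsd = sqrt(s2 / n), skew = s3 / n, min = mn, max = mx)
}

# maximum bipartite matching count by augmenting paths; adjacency built
# directly from the completeness rule (same type, distance < cutoff)
oracle_max_matching <- function(built, deposited, cutoff = 1.0) {
  bi <- which(!is.na(built$x)); di <- which(!is.na(deposited$x))
  adj <- lapply(bi, function(b) {
    d2 <- (built$x[b] - deposited$x[di])^2 +
      (built$y[b] - deposited$y[di])^2 + (built$z[b] - deposited$z[di])^2
    di[sqrt(d2) < cutoff & deposited$residue_type[di] == built$residue_type[b]]
  })
  match_d <- integer(0)
  match_of <- function(d) {
    i <- which(names(match_d) == as.character(d))
    if (length(i)) match_d[[i]] else 0L
  }
  aug <- function(b, env) {
    for (d in adj[[b]]) if (!env$seen[[as.character(d)]]) {
      env$seen[[as.character(d)]] <- TRUE
      m <- match_of(d)
      if (m == 0L || aug(m, env)) {
        match_d[[as.character(d)]] <<- b
        return(TRUE)
      }
    }
    FALSE
  }
  cnt <- 0L
  all_d <- unique(unlist(adj))
  for (b in seq_along(adj)) {
    env <- new.env()
    env$seen <- stats::setNames(as.list(rep(FALSE, length(all_d))),
                                as.character(all_d))
    if (length(adj[[b]]) && aug(b, env)) cnt <- cnt + 1L
  }
  cnt
}

# checks the anchored grouping rule directly against its definition
oracle_check_grouping <- function(widths, groups, tolerance = 0.05) {
  if (length(widths) != length(groups)) return(FALSE)
  if (is.unsorted(widths)) return(FALSE)
  g <- 0L; anchor <- NA_real_
  for (i in seq_along(widths)) {
    open_new <- is.na(anchor) || widths[i] > anchor * (1 + tolerance)
    if (open_new) { g <- g + 1L; anchor <- widths[i] }
    if (groups[i] != g) return(FALSE)
  }
  TRUE
}

# protein-like random completeness instances: deposited C-alpha on a path
# with spacing >= 3.5 A, built = displaced copies straddling the cutoff,
# plus type errors, decoys and duplicate builds near one residue
random_match_instance <- function(n, seed) {
  set.seed(seed)
  aa <- c("ALA", "GLY", "SER", "LEU", "VAL")
  x <- seq_len(n) * 3.8
  y <- runif(n, -0.3, 0.3); z <- runif(n, -0.3, 0.3)
  types <- sample(aa, n, replace = TRUE)
  deposited <- structure_model(data.frame(
    chain_id = "A", seq_num = seq_len(n), insertion_code = "",
    residue_type = types, x = x, y = y, z = z, stringsAsFactors = FALSE))
  rows <- list(); serial <- 0L
  add <- function(ty, px, py, pz) {
    serial <<- serial + 1L
    rows[[serial]] <<- data.frame(chain_id = "B", seq_num = serial,
                                  insertion_code = "", residue_type = ty,
                                  x = px, y = py, z = pz,
                                  stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    r <- runif(1)
    if (r < 0.5) {                       # displaced copy, 0 - 1.5 A
      d <- runif(1, 0, 1.5); u <- rnorm(3); u <- u / sqrt(sum(u^2))
      add(types[i], x[i] + d * u[1], y[i] + d * u[2], z[i] + d * u[3])
      if (runif(1) < 0.3) {              # duplicate build near same residue
        d2 <- runif(1, 0, 0.9); u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
        add(types[i], x[i] + d2 * u2[1], y[i] + d2 * u2[2], z[i] + d2 * u2[3])
      }
    } else if (r < 0.7) {                # wrong type at the right place
      add(sample(setdiff(aa, types[i]), 1), x[i], y[i], z[i])
    }                                    # else omitted
  }
  for (k in seq_len(sample(0:3, 1)))     # decoys anywhere
    add(sample(aa, 1), runif(1, 0, n * 3.8), runif(1, -5, 5), runif(1, -5, 5))
  built <- if (length(rows)) structure_model(do.call(rbind, rows)) else
    structure_model(data.frame(chain_id = character(), seq_num = integer(),
                               insertion_code = character(),
                               residue_type = character(), x = numeric(),
                               y = numeric(), z = numeric(),
                               stringsAsFactors = FALSE))
  list(built = built, deposited = deposited)
}

make_test_model <- function(n = 5, seed = 1) {
  set.seed(seed)
  structure_model(data.frame(
    chain_id = "A", seq_num = seq_len(n), insertion_code = "",
    residue_type = sample(c("ALA", "GLY", "SER"), n, replace = TRUE),
    # coordinates on the PDB 3-decimal grid so text round-trips are exact
    x = round(seq_len(n) * 3.8 + runif(n, -0.3, 0.3), 3),
    y = round(runif(n, -0.4, 0.4), 3),
    z = round(runif(n, -0.4, 0.4), 3),
    stringsAsFactors = FALSE))
}
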