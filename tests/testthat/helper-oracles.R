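# Independent brute-force oracles used across the test files. These stay
# deliberately naive and separate from the package's own implementations.

# Wiener index by all-pairs breadth-first search over an adjacency list.
oracle_wiener <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  tot <- 0L
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L; q <- c(q, w)
      }
    }
    tot <- tot + sum(dist[dist > 0L])
  }
  as.integer(tot / 2L)
}

# random connected graph on n nodes: a random spanning tree plus extra edges
random_connected_graph <- function(n, extra = 2L) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1),
                             integer(1)))
  for (k in seq_len(extra)) {
    ij <- sort(sample.int(n, 2))
    edges <- rbind(edges, ij)
  }
  edges[!duplicated(t(apply(edges, 1, sort))), , drop = FALSE]
}

# metric formulas written out longhand
oracle_metrics <- function(y, yhat, ytrain) {
  n <- length(y)
  rmse <- sqrt(sum((yhat - y)^2) / n)
  r <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  ry <- rank(y); rp <- rank(yhat)
  rho <- sum((ry - mean(ry)) * (rp - mean(rp))) /
    sqrt(sum((ry - mean(ry))^2) * sum((rp - mean(rp))^2))
  r2 <- 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
  qf32 <- 1 - (sum((yhat - y)^2) / n) /
    (sum((ytrain - mean(ytrain))^2) / length(ytrain))
  c(RMSE = rmse, r = r, rho = rho, R2 = r2, QF32 = qf32)
}

# a minimal one-residue PDB text fixture (glycine backbone, 4 atoms)
pdb_fixture_lines <- function() {
  c("HEADER    TEST FIXTURE",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   GLY A   1       3.231   1.536   0.000  1.00 10.00           O",
    "END")
}

write_pdb_fixture <- function(lines = pdb_fixture_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# synthetic protein built directly from an atom table
protstruct_from_atoms <- function(df) {
  defaults <- list(record = "ATOM", occupancy = 1, hetero = FALSE,
                   chain = "A")
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  structure(list(atoms = df, path = NA_character_), class = "protstruct")
}
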