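# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the group oracle classifies from the abstract
# multiplication table (no axis geometry), and the clustering oracle is a
# plain union-find over an explicit edge list (no graph library).

# --- exhaustive multiplication-table point-group oracle ----------------------

# index of the element of `Rs` matching M, or NA
mt_index <- function(Rs, M, tol = 1e-6) {
  d <- vapply(Rs, function(R) max(abs(R - M)), numeric(1))
  i <- which.min(d)
  if (d[i] < tol) i else NA_integer_
}

# order of element i from the multiplication table alone
mt_element_order <- function(Rs, i) {
  id <- mt_index(Rs, diag(3))
  cur <- i
  for (n in 1:100) {
    if (cur == id) return(n)
    cur <- mt_index(Rs, Rs[[cur]] %*% Rs[[i]])
    if (is.na(cur)) return(NA_integer_)
  }
  NA_integer_
}

# classify a closed rotation set purely from group structure:
# cyclic iff an element has order N; Klein four-group is D2; dihedral groups
# have an order-N/2 element plus >= N/2 involutions; T, O, I recognized by
# order and element-order spectrum
oracle_classify <- function(ops) {
  Rs <- lapply(ops, function(o) if (inherits(o, "rigid_operator")) o$R else o)
  N <- length(Rs)
  # closure must hold for the table to be meaningful
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (is.na(mt_index(Rs, Rs[[i]] %*% Rs[[j]]))) stop("oracle: set not closed")
    }
  }
  ords <- vapply(seq_len(N), function(i) mt_element_order(Rs, i), integer(1))
  if (N == 1L) return("C1")
  if (max(ords) == N) return(paste0("C", N))
  if (N == 4L && all(ords <= 2L)) return("D2")
  if (N == 60L) return("I")
  if (N == 24L && max(ords) == 4L) return("O")
  if (N == 12L && max(ords) == 3L) return("T")
  n <- N %/% 2L
  if (N %% 2L == 0L && any(ords == n) && sum(ords == 2L) >= n) {
    return(paste0("D", n))
  }
  stop("oracle: unrecognized group")
}

# --- union-find single-linkage oracle ----------------------------------------

uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition (for comparison irrespective of labels)
partition_key <- function(ids, membership) {
  groups <- split(ids, membership)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")), collapse = ";")
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about(ax, stats::runif(1, 0, 2 * pi))
}
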