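# Independent oracles used across the suite. The folding oracle
# enumerates every legal secondary structure of a short sequence and
# scores it by explicit loop decomposition; the duplex oracle enumerates
# every monotone intermolecular pairing; the rule oracle re-evaluates the
# target rules with plain loops. They share only the published energy
# tables with the implementation, never its search code.

rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_pt <- function(a, b) {
  m <- c(AU = 1, UA = 2, GC = 3, CG = 4, GU = 5, UG = 6)
  v <- m[paste0(a, b)]
  ifelse(is.na(v), 0L, as.integer(v))
}

oracle_enum_structures <- function(v, i, j) {
  if (i >= j) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  for (s in oracle_enum_structures(v, i + 1L, j)) {
    out[[length(out) + 1L]] <- s
  }
  k0 <- i + 4L
  if (k0 <= j) {
    for (k in k0:j) {
      if (oracle_pt(v[i], v[k]) == 0) next
      left <- oracle_enum_structures(v, i + 1L, k - 1L)
      right <- if (k + 1L <= j) oracle_enum_structures(v, k + 1L, j)
               else list(matrix(integer(0), ncol = 2))
      for (s1 in left) {
        for (s2 in right) {
          out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), s1,
                                           s2)
        }
      }
    }
  }
  out
}

oracle_structure_energy <- function(v, pr, par) {
  if (nrow(pr) == 0) return(0)
  pr <- pr[order(pr[, 1]), , drop = FALSE]
  total <- 0
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]
    j <- pr[r, 2]
    inside <- pr[pr[, 1] > i & pr[, 2] < j, , drop = FALSE]
    if (nrow(inside)) {
      top <- rep(TRUE, nrow(inside))
      for (q in seq_len(nrow(inside))) {
        top[q] <- !any(inside[, 1] < inside[q, 1] &
                         inside[, 2] > inside[q, 2])
      }
      inside <- inside[top, , drop = FALSE]
    }
    B <- nrow(inside)
    ptO <- oracle_pt(v[i], v[j])
    if (B == 0) {
      L <- j - i - 1
      if (L < par$min_hairpin) return(NA_real_)
      total <- total + par$hairpin[L]
    } else if (B == 1) {
      k <- inside[1, 1]
      l <- inside[1, 2]
      l1 <- k - i - 1
      l2 <- j - l - 1
      if (l1 == 0 && l2 == 0) {
        total <- total + par$stack[ptO, oracle_pt(v[k], v[l])]
      } else if (l1 + l2 > par$max_interior) {
        return(NA_real_)
      } else if (l1 == 0 || l2 == 0) {
        total <- total + par$bulge[l1 + l2]
      } else {
        total <- total + par$internal[l1 + l2]
      }
    } else {
      U <- (j - i - 1) - sum(inside[, 2] - inside[, 1] + 1)
      total <- total + par$ml_a + par$ml_b * (B + 1) + par$ml_c * U
    }
  }
  total
}

oracle_fold_mfe <- function(seq, par = energy_parameters()) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  structs <- oracle_enum_structures(v, 1L, length(v))
  e <- vapply(structs, function(pr) {
    x <- oracle_structure_energy(v, pr, par)
    if (is.na(x)) Inf else x
  }, numeric(1))
  min(0, min(e)) / 10
}

oracle_duplex_mfe <- function(a, b, par = energy_parameters()) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(va)
  m <- length(vb)
  best <- 0
  ext <- function(i, j, acc) {
    if (acc < best) best <<- acc
    if (i >= n || j <= 1) return(invisible(NULL))
    for (k in (i + 1):n) {
      l1 <- k - i - 1
      if (l1 > par$max_interior) break
      for (l in (j - 1):1) {
        l2 <- j - l - 1
        if (l1 + l2 > par$max_interior) break
        p2 <- oracle_pt(va[k], vb[l])
        if (p2 == 0) next
        p1 <- oracle_pt(va[i], vb[j])
        g <- if (l1 == 0 && l2 == 0) par$stack[p1, p2]
             else if (l1 == 0 || l2 == 0) par$bulge[l1 + l2]
             else par$internal[l1 + l2]
        ext(k, l, acc + g)
      }
    }
  }
  for (i in 1:n) {
    for (j in m:1) {
      if (oracle_pt(va[i], vb[j]) > 0) ext(i, j, 0)
    }
  }
  best / 10
}

# plain-loop re-derivation of the weighted-mismatch rules (strict
# defaults)
oracle_rule_check <- function(mirna, site) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("T", "U", toupper(site)), "")[[1]]
  L <- length(m)
  val <- numeric(L)
  for (p in seq_len(L)) {
    pair <- paste0(m[p], s[L - p + 1])
    val[p] <- if (pair %in% c("AU", "UA", "GC", "CG")) 0
              else if (pair %in% c("GU", "UG")) 0.5 else 1
  }
  run <- 0
  maxrun <- 0
  for (p in seq_len(L)) {
    run <- if (val[p] >= 0.5) run + 1 else 0
    maxrun <- max(maxrun, run)
  }
  r3 <- TRUE
  for (p in 2:11) {
    if (val[p] == 1 && val[p + 1] == 1) r3 <- FALSE
  }
  r <- c(sum(val) <= 4, maxrun <= 2, r3,
         val[10] == 0 && val[11] == 0, sum(val[1:12]) <= 2.5)
  list(val = val, total = sum(val), r = r, pass = all(r))
}
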