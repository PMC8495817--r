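# Independent oracles, coded before the operations they check.

# ---- alignment oracles -------------------------------------------------

default_sc <- function() list(match = 2L, mismatch = -3L, gap_open = -5L,
                              gap_extend = -2L)

# Plain-R dynamic-programming oracle for ends-free affine alignment under the
# documented objective: maximal score, then fewest internal gap columns, then
# the fixed preference (substitution > gap-in-subject > gap-in-query;
# endpoints prefer the longest overlap).  Returns score and overlap-region
# statistics computed from its own traceback.
oracle_align <- function(a, b, sc = default_sc()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEGS <- -1e9
  SM <- SX <- SY <- matrix(NEGS, m + 1, n + 1)
  GM <- GX <- GY <- matrix(0L, m + 1, n + 1)
  PMp <- PXp <- PYp <- matrix(-1L, m + 1, n + 1)
  bet <- function(s1, g1, s2, g2) (s1 > s2) || (s1 == s2 && g1 < g2)
  goe <- sc$gap_open + sc$gap_extend
  for (i in 1:m) {
    for (j in 1:n) {
      # cell (i, j) stored at [i+1, j+1]
      # M from (i-1, j-1)
      cands <- list(c(SM[i, j], GM[i, j], 1), c(SX[i, j], GX[i, j], 2),
                    c(SY[i, j], GY[i, j], 3))
      if (i == 1 || j == 1) cands <- c(cands, list(c(0, 0, 0)))
      best <- NULL
      for (cd in cands) {
        if (cd[1] <= NEGS) next
        if (is.null(best) || bet(cd[1], cd[2], best[1], best[2])) best <- cd
      }
      if (!is.null(best)) {
        s <- if (av[i] == bv[j]) sc$match else sc$mismatch
        SM[i + 1, j + 1] <- best[1] + s
        GM[i + 1, j + 1] <- best[2]
        PMp[i + 1, j + 1] <- best[3]
      }
      # X from (i-1, j): a[i] over gap
      cands <- list(c(SM[i, j + 1] + goe, GM[i, j + 1] + 1, 1),
                    c(SX[i, j + 1] + sc$gap_extend, GX[i, j + 1] + 1, 2),
                    c(SY[i, j + 1] + goe, GY[i, j + 1] + 1, 3))
      if (i == 1) cands <- c(cands, list(c(goe, 1, 0)))
      best <- NULL
      for (cd in cands) {
        if (cd[1] <= NEGS / 2) next
        if (is.null(best) || bet(cd[1], cd[2], best[1], best[2])) best <- cd
      }
      if (!is.null(best)) {
        SX[i + 1, j + 1] <- best[1]; GX[i + 1, j + 1] <- best[2]
        PXp[i + 1, j + 1] <- best[3]
      }
      # Y from (i, j-1): gap over b[j]
      cands <- list(c(SM[i + 1, j] + goe, GM[i + 1, j] + 1, 1),
                    c(SX[i + 1, j] + goe, GX[i + 1, j] + 1, 2),
                    c(SY[i + 1, j] + sc$gap_extend, GY[i + 1, j] + 1, 3))
      if (j == 1) cands <- c(cands, list(c(goe, 1, 0)))
      best <- NULL
      for (cd in cands) {
        if (cd[1] <= NEGS / 2) next
        if (is.null(best) || bet(cd[1], cd[2], best[1], best[2])) best <- cd
      }
      if (!is.null(best)) {
        SY[i + 1, j + 1] <- best[1]; GY[i + 1, j + 1] <- best[2]
        PYp[i + 1, j + 1] <- best[3]
      }
    }
  }
  # endpoint: degenerate no-overlap alignment always available at (score 0)
  bestS <- 0; bestG <- 0; bi <- m; bj <- 0; bstate <- 0
  consider <- function(i, j, st, s, g) {
    if (s <= NEGS / 2) return()
    take <- FALSE
    if (bet(s, g, bestS, bestG)) take <- TRUE
    else if (s == bestS && g == bestG && st != 0) {
      if (bstate == 0) take <- TRUE
      else if (i + j > bi + bj) take <- TRUE
      else if (i + j == bi + bj && i > bi) take <- TRUE
      else if (i + j == bi + bj && i == bi && st < bstate) take <- TRUE
    }
    if (take) {
      bestS <<- s; bestG <<- g; bi <<- i; bj <<- j; bstate <<- st
    }
  }
  for (i in 1:m) {
    consider(i, n, 1, SM[i + 1, n + 1], GM[i + 1, n + 1])
    consider(i, n, 2, SX[i + 1, n + 1], GX[i + 1, n + 1])
    consider(i, n, 3, SY[i + 1, n + 1], GY[i + 1, n + 1])
  }
  if (n > 1) {
    for (j in 1:(n - 1)) {
      consider(m, j, 1, SM[m + 1, j + 1], GM[m + 1, j + 1])
      consider(m, j, 2, SX[m + 1, j + 1], GX[m + 1, j + 1])
      consider(m, j, 3, SY[m + 1, j + 1], GY[m + 1, j + 1])
    }
  }
  # traceback to gapped strings
  if (bstate == 0) {
    ga <- c(av, rep("-", n)); gb <- c(rep("-", m), bv)
  } else {
    ga <- character(0); gb <- character(0)
    if (bj == n) {
      if (bi < m) { ga <- av[(bi + 1):m]; gb <- rep("-", m - bi) }
    } else {
      if (bj < n) { ga <- rep("-", n - bj); gb <- bv[(bj + 1):n] }
    }
    i <- bi; j <- bj; st <- bstate
    while (st != 0) {
      if (st == 1) {
        pred <- PMp[i + 1, j + 1]
        ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1; j <- j - 1
      } else if (st == 2) {
        pred <- PXp[i + 1, j + 1]
        ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1
      } else {
        pred <- PYp[i + 1, j + 1]
        ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1
      }
      st <- pred
    }
    if (i > 0) { ga <- c(av[1:i], ga); gb <- c(rep("-", i), gb) }
    if (j > 0) { ga <- c(rep("-", j), ga); gb <- c(bv[1:j], gb) }
  }
  st <- oracle_region_stats(ga, gb)
  c(list(score = bestS), st)
}

oracle_region_stats <- function(ga, gb) {
  resa <- which(ga != "-"); resb <- which(gb != "-")
  if (!length(resa) || !length(resb)) {
    return(list(n_ident = 0L, n_denom = 0L, q_res = 0L))
  }
  lo <- max(min(resa), min(resb)); hi <- min(max(resa), max(resb))
  if (lo > hi) return(list(n_ident = 0L, n_denom = 0L, q_res = 0L))
  ga <- ga[lo:hi]; gb <- gb[lo:hi]
  list(n_ident = sum(ga != "-" & ga == gb), n_denom = hi - lo + 1L,
       q_res = sum(ga != "-"))
}

# Exhaustive enumeration of every monotone alignment (move types: 1 = both,
# 2 = a over gap, 3 = gap over b), scoring each column list with free terminal
# runs and affine internal gaps.  Returns the maximal score, the minimal
# internal gap-column count among score-optima, and the set of stats tuples
# achieved by (score, gap)-optimal alignments.  Feasible for short strings.
enum_align <- function(a, b, sc = default_sc()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  best <- list(score = -Inf, gaps = Inf, stats = list())
  score_cols <- function(cols) {
    # residue columns per row
    a_res <- cols != 3L; b_res <- cols != 2L
    fa <- match(TRUE, a_res); la <- length(cols) + 1L - match(TRUE, rev(a_res))
    fb <- match(TRUE, b_res); lb <- length(cols) + 1L - match(TRUE, rev(b_res))
    lo <- max(fa, fb); hi <- min(la, lb)
    if (is.na(lo) || is.na(hi) || lo > hi) {
      return(list(score = 0L, gaps = 0L, n_ident = 0L, n_denom = 0L, q_res = 0L))
    }
    cc <- cols[lo:hi]
    ai <- cumsum(cols != 3L)[lo:hi]  # index into av at each consuming column
    bi <- cumsum(cols != 2L)[lo:hi]
    s <- 0L; gaps <- 0L; n_ident <- 0L
    k <- 1L
    while (k <= length(cc)) {
      if (cc[k] == 1L) {
        eq <- av[ai[k]] == bv[bi[k]]
        s <- s + if (eq) sc$match else sc$mismatch
        if (eq) n_ident <- n_ident + 1L
        k <- k + 1L
      } else {
        run_type <- cc[k]
        len <- 0L
        while (k <= length(cc) && cc[k] == run_type) { len <- len + 1L; k <- k + 1L }
        s <- s + sc$gap_open + len * sc$gap_extend
        gaps <- gaps + len
      }
    }
    list(score = s, gaps = gaps, n_ident = n_ident,
         n_denom = hi - lo + 1L, q_res = sum(cc != 3L))
  }
  rec <- function(i, j, cols) {
    if (i == m && j == n) {
      r <- score_cols(cols)
      if (r$score > best$score ||
          (r$score == best$score && r$gaps < best$gaps)) {
        best <<- list(score = r$score, gaps = r$gaps,
                      stats = list(c(r$n_ident, r$n_denom, r$q_res)))
      } else if (r$score == best$score && r$gaps == best$gaps) {
        best$stats[[length(best$stats) + 1L]] <<- c(r$n_ident, r$n_denom, r$q_res)
      }
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, c(cols, 1L))
    if (i < m) rec(i + 1L, j, c(cols, 2L))
    if (j < n) rec(i, j + 1L, c(cols, 3L))
  }
  rec(0L, 0L, integer(0))
  best$stats <- unique(best$stats)
  best
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

# ---- monophyly oracle --------------------------------------------------

# Brute-force bipartition enumeration: remove each edge in turn and flood-fill
# the two components of the tree graph.  Independent of ape's clade machinery.
oracle_monophyly <- function(tree, species_of, min_support = 70) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  side_tips <- function(start, banned_from, banned_to) {
    seen <- logical(nnode); seen[start] <- TRUE
    stack <- start
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in adj[[x]]) {
        if ((x == banned_from && y == banned_to) ||
            (x == banned_to && y == banned_from)) next
        if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
      }
    }
    which(seen[seq_len(ntip)])
  }
  sp <- unname(species_of[tree$tip.label])
  species <- sort(unique(sp))
  out <- data.frame(species = species, n_tips = 0L, is_monophyletic = NA,
                    support = NA_real_, counted_as_MS = FALSE)
  for (s in seq_along(species)) {
    tset <- which(sp == species[s])
    out$n_tips[s] <- length(tset)
    if (length(tset) < 2L) next
    mono <- FALSE; supp <- NA_real_
    if (length(tset) == ntip) {
      mono <- TRUE
    } else {
      direct <- NULL; compl <- NULL
      for (k in seq_len(nrow(tree$edge))) {
        u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
        tv <- side_tips(v, u, v)
        if (setequal(tv, tset) && is.null(direct)) direct <- v
        if (setequal(setdiff(seq_len(ntip), tv), tset) && is.null(compl)) compl <- v
      }
      v <- if (!is.null(direct)) direct else compl
      if (!is.null(v)) {
        mono <- TRUE
        supp <- if (v > ntip) sup[v - ntip] else NA_real_
      }
    }
    out$is_monophyletic[s] <- mono
    out$support[s] <- supp
    out$counted_as_MS[s] <- isTRUE(mono) && !is.na(supp) && supp >= min_support
  }
  out
}
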