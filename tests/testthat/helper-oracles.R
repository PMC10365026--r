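# Independent brute-force oracles. These re-derive each operation from its
# definition by direct enumeration (per-base scans, explicit loops), sharing
# no code with the implementation they check.

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    # step-up: smallest value of p_(k) * m / k over all k >= rank of i
    cands <- vapply(rank_i:m, function(k) p[o[k]] * m / k, numeric(1))
    adj[i] <- min(1, min(cands))
  }
  adj
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_concordant <- function(corr, de, fdr) {
  out <- list()
  for (i in seq_len(nrow(corr))) {
    g <- corr$gene_id[i]
    j <- which(de$gene_id == g)
    if (!length(j)) next
    r <- corr$r[i]; lfc <- de$log2fc[j]; padj <- de$padj[j]
    if (is.na(r) || padj > fdr) next
    if (r > 0 && lfc > 0) out[[g]] <- "+"
    if (r < 0 && lfc < 0) out[[g]] <- "-"
  }
  tibble::tibble(gene_id = as.character(names(out)),
                 direction = as.character(unlist(out, use.names = FALSE)))
}

oracle_kd_filter <- function(candidates, kd_tables, fdr, require_all) {
  keep <- character(0)
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene_id[i]
    want <- if (candidates$direction[i] == "+") "-" else "+"
    ok <- vapply(kd_tables, function(de) {
      j <- which(de$gene_id == g)
      length(j) == 1 && de$padj[j] <= fdr &&
        ((want == "-" && de$log2fc[j] < 0) || (want == "+" && de$log2fc[j] > 0))
    }, logical(1))
    pass <- if (require_all) all(ok) else any(ok)
    if (pass) keep <- c(keep, g)
  }
  keep
}

# Per-base consensus scan on small coordinates.
oracle_consensus <- function(replicates, min_rep, max_coord = 400) {
  chroms <- unique(unlist(lapply(replicates, function(x) x$chrom)))
  out <- list()
  for (cc in sort(chroms)) {
    support <- integer(max_coord)
    for (rep in replicates) {
      covered <- logical(max_coord)
      px <- rep[rep$chrom == cc, , drop = FALSE]
      for (j in seq_len(nrow(px))) {
        if (px$end[j] > px$start[j]) {
          covered[(px$start[j] + 1):px$end[j]] <- TRUE  # bp b = [b-1, b)
        }
      }
      support <- support + covered
    }
    ok <- support >= min_rep
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k] - 1L; e <- ends[k]
      scores <- unlist(lapply(replicates, function(rep) {
        px <- rep[rep$chrom == cc, , drop = FALSE]
        px$score[px$start < e & s < px$end]
      }))
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = cc, start = s, end = e,
        score = mean(scores, na.rm = TRUE))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

oracle_stitch <- function(peaks, stitch_distance) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && peaks$chrom[i] == peaks$chrom[j]) {
      gap <- max(peaks$start[i], peaks$start[j]) -
        min(peaks$end[i], peaks$end[j])
      if (gap < stitch_distance) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(comp), function(g) {
    m <- comp == g
    tibble::tibble(chrom = peaks$chrom[m][1], start = min(peaks$start[m]),
                   end = max(peaks$end[m]), n_constituents = sum(m))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

oracle_se_cutpoint <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  best <- -Inf; i_star <- NA
  for (i in seq_len(n)) {
    if (x[i] - y[i] >= best) { best <- x[i] - y[i]; i_star <- i }  # ties -> last
  }
  sum(signals > s[i_star])
}

oracle_tf_fractions <- function(tf, se_tbl) {
  hit <- function(a, b) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom == b$chrom[j] && a$start < b$end[j] && b$start[j] < a$end
    }, logical(1)))
  }
  se <- se_tbl[se_tbl$is_SE, , drop = FALSE]
  ty <- se_tbl[!se_tbl$is_SE, , drop = FALSE]
  f1 <- if (!nrow(se)) NA_real_ else mean(vapply(seq_len(nrow(se)), function(i)
    hit(se[i, ], tf), logical(1)))
  f2 <- if (!nrow(ty)) NA_real_ else mean(vapply(seq_len(nrow(ty)), function(i)
    hit(ty[i, ], tf), logical(1)))
  f3 <- if (!nrow(se)) NA_real_ else if (!nrow(tf)) 0 else
    mean(vapply(seq_len(nrow(tf)), function(i) hit(tf[i, ], se), logical(1)))
  c(f1, f2, f3)
}

# Regulatory domains by per-base outward walk on small coordinates.
oracle_domains <- function(gm, basal_up, basal_down, max_extension, chrom_len) {
  basal <- data.frame(
    gene_id = gm$gene_id, chrom = gm$chrom,
    s = ifelse(gm$strand == "+", gm$tss - basal_up, gm$tss - basal_down),
    e = ifelse(gm$strand == "+", gm$tss + basal_down, gm$tss + basal_up))
  basal$s <- pmax(basal$s, 0)
  basal$e <- pmin(basal$e, chrom_len)
  res <- list()
  for (i in seq_len(nrow(gm))) {
    bs <- basal$s[i]; be <- basal$e[i]
    in_foreign <- function(x) {
      any(basal$chrom == gm$chrom[i] & basal$gene_id != gm$gene_id[i] &
            basal$s <= x & x < basal$e)
    }
    lo <- bs
    while (lo > 0 && lo > gm$tss[i] - max_extension && !in_foreign(lo - 1)) {
      lo <- lo - 1
    }
    hi <- be
    while (hi < chrom_len && hi < gm$tss[i] + max_extension && !in_foreign(hi)) {
      hi <- hi + 1
    }
    res[[i]] <- tibble::tibble(gene_id = gm$gene_id[i], basal_start = bs,
                               basal_end = be, ext_start = lo, ext_end = hi)
  }
  dplyr::bind_rows(res)
}

oracle_assign <- function(peaks, domains) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    for (j in seq_len(nrow(domains))) {
      if (peaks$chrom[i] == domains$chrom[j] &&
          domains$ext_start[j] <= mid && mid < domains$ext_end[j]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          peak_idx = i, gene_id = domains$gene_id[j])
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(peak_idx = integer(), gene_id = character()))
  }
  dplyr::bind_rows(rows)
}

# Hand-built log-rank O/E/V table, one event time at a time.
oracle_logrank <- function(times, events, group1) {
  O <- E <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chi = if (V > 0) (O - E)^2 / V else 0)
}

random_peakset <- function(n, chroms = c("chrA", "chrB"), max_coord = 380,
                           max_len = 40) {
  s <- sample.int(max_coord - max_len, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = s, end = s + sample.int(max_len, n, replace = TRUE),
                 name = sprintf("p%03d", seq_len(n)),
                 score = round(runif(n, 1, 100), 2))
}
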