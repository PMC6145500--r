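# Independent oracles used by the tests. These deliberately avoid the
# package's dynamic-programming code paths: structures are enumerated
# explicitly and scored by loop decomposition.

oraclePairOK <- function(a, b)
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")

# all pseudoknot-free structures (lists of pair index vectors), min
# hairpin loop 3
enumStructures <- function(s) {
  ch <- strsplit(chartr("U", "T", toupper(s)), "")[[1]]
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (k > j) break
      if (!oraclePairOK(ch[i], ch[k])) next
      ins <- rec(i + 1L, k - 1L)
      outs <- rec(k + 1L, j)
      for (a in ins) for (b in outs)
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
    memo[[key]] <- out
    out
  }
  if (n < 5L) return(list(list()))
  rec(1L, n)
}

oracleLoopPen <- function(model, type, size) {
  tab <- methods::slot(model, type)
  sizes <- as.integer(names(tab))
  if (size %in% sizes) return(unname(tab[[as.character(size)]]))
  hi <- max(sizes)
  if (size > hi)
    return(unname(tab[[as.character(hi)]]) + 1.75 * 0.616 * log(size / hi))
  Inf
}

# free energy of one explicit structure by loop decomposition (in exact
# hundredths, like the engine)
oracleScore <- function(s, pairs, model) {
  ch <- strsplit(chartr("U", "T", toupper(s)), "")[[1]]
  n <- length(ch)
  if (!length(pairs)) return(0)
  pt <- integer(n)
  for (p in pairs) { pt[p[1]] <- p[2]; pt[p[2]] <- p[1] }
  ptype <- function(i, j) {
    m <- c(A = "A", C = "C", G = "G", T = "U")
    paste0(m[[ch[i]]], m[[ch[j]]])
  }
  e100 <- function(x) round(x * 100)
  total <- 0
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    kids <- list()
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else k <- k + 1L
    }
    unp <- (j - i - 1L) -
      sum(vapply(kids, function(q) q[2] - q[1] + 1L, integer(1)))
    if (length(kids) == 0L) {
      total <- total + e100(oracleLoopPen(model, "hairpin", j - i - 1L))
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L)
        total <- total + e100(model@stack[ptype(i, j), ptype(k, l)])
      else if (n1 == 0L || n2 == 0L)
        total <- total + e100(oracleLoopPen(model, "bulge", n1 + n2))
      else
        total <- total + e100(oracleLoopPen(model, "internal", n1 + n2) +
                                min(model@asymMax,
                                    model@asymPerNt * abs(n1 - n2)))
    } else {
      total <- total + e100(model@mlOffset + model@mlBranch) +
        length(kids) * e100(model@mlBranch) +
        unp * e100(model@mlUnpaired)
    }
  }
  total / 100
}

oracleMFE <- function(s, model) {
  vals <- vapply(enumStructures(s), function(p) oracleScore(s, p, model),
                 numeric(1))
  min(0, vals)
}

# exhaustive hypergeometric upper tail by enumerating all draws of size n
# from N labelled genes
oracleHyper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hitsPer <- apply(draws, 2, function(d) sum(d <= K))
  mean(hitsPer >= k)
}

randomSeq <- function(n, prob = rep(0.25, 4))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")

dinucCounts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
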