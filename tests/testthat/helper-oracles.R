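# Independent oracles used across the suite. These deliberately avoid the
# package's LP layer: the vertex enumerator uses only dense linear algebra,
# so it can certify the optimization code from outside.

# Exact maximizer of c'v subject to S v = 0, 0 <= v <= ub, by enumerating
# candidate vertices: every subset of variables is fixed at one of its
# bounds, the remaining (at most rank(S)) are solved from the equality
# system, and infeasible candidates are discarded. Exponential, for tiny
# networks only.
bruteForceLPMax <- function(S, ub, cc) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(n <= 9)
  r <- qr(S)$rank
  best <- -Inf
  states <- expand.grid(rep(list(0:2), n))   # 0 = at 0, 1 = at ub, 2 = free
  for (k in seq_len(nrow(states))) {
    st <- as.integer(states[k, ])
    free <- which(st == 2)
    if (length(free) > r) next
    v <- ifelse(st == 1, ub, 0)
    if (length(free) > 0) {
      Sf <- S[, free, drop = FALSE]
      rhs <- -S[, -free, drop = FALSE] %*% v[-free]
      sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[free] <- sol
    }
    if (max(abs(S %*% v)) > 1e-7) next
    if (min(v) < -1e-7 || max(v - ub) > 1e-7) next
    val <- sum(cc * v)
    if (val > best) best <- val
  }
  best
}

# Random GPR expression tree over the given genes, returned as rule text.
randomGprRule <- function(genes, depth = 2) {
  if (depth == 0 || runif(1) < 0.3)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- vapply(seq_len(k), function(i)
    randomGprRule(genes, depth - 1), character(1))
  paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}

# Direct R evaluation of a rule under a knockout, via substitution into a
# parsed R expression -- independent of the package's recursive evaluator.
gprTruthOracle <- function(rule, genes, knockedOut) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- rule
  env <- new.env()
  for (i in seq_along(genes)) {
    nm <- paste0(".g", i)
    expr <- gsub(paste0("\\b", genes[i], "\\b"), nm, expr)
    assign(nm, !(genes[i] %in% knockedOut), envir = env)
  }
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  eval(parse(text = expr), envir = env)
}

# Minimum-weight addition sets (up to maxSize) that restore growth,
# by exhaustive subset enumeration over the candidate database.
bruteForceRestore <- function(model, database, media, genes, weights,
                              threshold = 0.02, maxSize = 2) {
  cand <- reactionIds(database)
  best <- Inf; sets <- list()
  for (size in seq_len(min(maxSize, length(cand)))) {
    for (set in utils::combn(cand, size, simplify = FALSE)) {
      m2 <- applyKnockout(addReactions(model, database, only = set), genes)
      if (limedFBA(m2, media)@objective > threshold) {
        w <- sum(weights[set])
        if (w < best - 1e-12) { best <- w; sets <- list(set) }
        else if (abs(w - best) <= 1e-12) sets <- c(sets, list(set))
      }
    }
  }
  list(weight = best, sets = sets)
}

# Minimum-weight removal sets (up to maxSize) that suppress growth.
bruteForceSuppress <- function(model, media, genes, weights,
                               threshold = 0.02, maxSize = 3) {
  rxn <- reactions(model)
  removable <- setdiff(rxn$id[!rxn$curated & is.finite(weights[rxn$id])],
                       objectiveReaction(model))
  ko <- applyKnockout(model, genes)
  best <- Inf; sets <- list()
  for (size in seq_len(min(maxSize, length(removable)))) {
    for (set in utils::combn(removable, size, simplify = FALSE)) {
      m2 <- ko
      j <- match(set, reactionIds(m2))
      b <- bounds(m2); b[j, ] <- 0; bounds(m2) <- b
      if (limedFBA(m2, media)@objective <= threshold) {
        w <- sum(weights[set])
        if (w < best - 1e-12) { best <- w; sets <- list(set) }
        else if (abs(w - best) <= 1e-12) sets <- c(sets, list(set))
      }
    }
  }
  list(weight = best, sets = sets)
}

# Blocked set according to per-reaction flux maximization (the FVA oracle)
# over the dilution-corrected region with unlimited nutrients. The oracle
# uses the same operational threshold as the goal program ("can the
# reaction carry delta = 1e-3 units of flux"): under dilution, tiny
# nonzero maxima exist on a continuum, so the two classifications are only
# comparable against a shared definition of carrying flux.
fvaBlockedChildren <- function(model, spec, delta = 1e-3) {
  opened <- farm:::.openNutrients(model, "all", spec@vMax)
  im <- splitReversible(opened)
  fv <- fluxVariability(im, spec = spec, tol = delta * (1 - 1e-6))
  fv$reaction[fv$blocked]
}
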