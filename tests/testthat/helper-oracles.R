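# Independent oracles used to cross-check the package's enumeration and LP
# machinery on small instances. They share no code path with the
# implementation: elementary modes come from exhaustive support-subset
# search with a numeric SVD kernel test, hitting sets from exhaustive
# subset search, and LP optima from pracma's simplex where available.

# numeric balance matrix (internal rows) of a model
num_S <- function(model) {
  S <- as.numeric(balance_matrix(model))
  matrix(S, nrow = sum(!model$mets$external))
}

# exhaustive elementary-mode oracle: a support J is elementary iff the
# kernel of S[, J] is one-dimensional and its generator is nonzero on all
# of J with a sign assignment respecting irreversibility.
brute_force_em_supports <- function(model, tol = 1e-8) {
  S <- num_S(model)
  blocked <- model$rxns$lb == 0 & model$rxns$ub == 0
  irrev <- !model$rxns$reversible | model$rxns$lb >= 0
  n <- n_reactions(model)
  found <- list()
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      J <- combs[, ci]
      if (any(blocked[J])) next
      if (any(vapply(found, function(f) all(f %in% J), TRUE))) next
      sub <- S[, J, drop = FALSE]
      sv <- svd(sub, nu = 0, nv = length(J))
      dims <- sum(c(sv$d, rep(0, length(J) - length(sv$d))) < tol)
      if (dims != 1) next
      w <- sv$v[, length(J)]
      if (any(abs(w) < tol)) next            # support would be smaller
      if (sum(w > 0) < sum(w < 0)) w <- -w   # canonical sign
      ir <- irrev[J]
      if (all(w[ir] > 0)) found[[length(found) + 1]] <- J
      else if (all(w[ir] < 0)) found[[length(found) + 1]] <- J
      else if (!any(ir)) found[[length(found) + 1]] <- J
    }
  }
  found
}

support_keys <- function(supports) {
  sort(vapply(supports, function(s) paste(sort(s), collapse = ","), ""))
}

# exhaustive minimal-hitting-set oracle over a small universe
brute_force_hitting_sets <- function(targets, universe) {
  hits <- list()
  n <- length(universe)
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      H <- universe[combs[, ci]]
      if (any(vapply(hits, function(h) all(h %in% H), TRUE))) next
      if (all(vapply(targets, function(tg) length(intersect(tg, H)) > 0, TRUE)))
        hits[[length(hits) + 1]] <- sort(H)
    }
  }
  hits
}

cutset_keys <- function(cs_list) {
  sort(vapply(cs_list, function(x) {
    cuts <- if (inherits(x, "cut_set")) x$cuts else x
    paste(sort(cuts), collapse = ",")
  }, ""))
}

# deterministic random test network: a substrate chain with branches,
# random internal bypasses and one or two reversible steps
random_network <- function(seed, n_internal = 4, n_rxns = 9) {
  set.seed(seed)
  ints <- paste0("M", seq_len(n_internal))
  mets <- data.frame(id = c("Sub", ints, "Prod1", "Prod2"),
                     external = c(TRUE, rep(FALSE, n_internal), TRUE, TRUE))
  rxns <- list(
    list(id = "U1", stoich = stats::setNames(c(-1, 1), c("Sub", ints[1]))),
    list(id = "E1", stoich = stats::setNames(c(-1, 1),
                                             c(ints[n_internal], "Prod1"))),
    list(id = "E2", stoich = stats::setNames(c(-1, 1), c(ints[1], "Prod2"))))
  k <- 0
  while (length(rxns) < n_rxns) {
    k <- k + 1
    pair <- sample(ints, 2)
    coefs <- sample(1:2, 2, replace = TRUE)
    rxns[[length(rxns) + 1]] <- list(
      id = sprintf("X%d", k),
      stoich = stats::setNames(c(-coefs[1], coefs[2]), pair),
      reversible = runif(1) < 0.25)
  }
  network_model(mets, rxns, id = sprintf("rand%d", seed))
}

photocore_ethanol_pair <- function() {
  list(day = make_photocore(photocore_params(products = "ethanol")),
       night = make_photocore(photocore_params(products = "ethanol",
                                               regime = "night")))
}
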