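#' Read and write stoichiometric models
#'
#' Two formats are supported. A plain TSV dialect (sections `# metabolites`
#' and `# reactions`, reaction equations like `2 A + 3/14 B => C`, `<=>`
#' for reversible) keeps coefficients as exact fractions and is convenient
#' for hand-edited toy networks. SBML (Level 3 core, with Level 2 fallbacks
#' on read) interoperates with the wider constraint-based modeling
#' ecosystem; boundary species are taken from the `boundaryCondition` flag,
#' with a configurable id-suffix rule and explicit list as fallbacks, and
#' flux bounds are read from either kinetic-law parameters
#' (`LOWER_BOUND`/`UPPER_BOUND`) or `fbc` attributes. Files written by
#' [write_sbml()] carry exact rational stoichiometry and tag/bound metadata
#' in a package annotation namespace so that a write/read cycle reproduces
#' the model losslessly.
#'
#' @param path file path.
#' @param external_suffix id suffixes marking external species when no
#'   `boundaryCondition` flag is present (read only).
#' @param external_ids explicit external species ids (read only).
#' @return [read_tsv_model()] and [read_sbml()] return a [network_model];
#'   the writers return `path` invisibly.
#' @name model_io
NULL

#' @rdname model_io
#' @export
read_tsv_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sec <- cumsum(grepl("^#", lines))
  headers <- trimws(sub("^#\\s*", "", lines[grepl("^#", lines)]))
  mets <- NULL; rxns <- list()
  for (s in seq_along(headers)) {
    body <- lines[sec == s & !grepl("^#", lines)]
    if (headers[s] == "metabolites") {
      if (!length(body)) { mets <- data.frame(id = character(), external = logical()); next }
      parts <- strsplit(body, "\t", fixed = TRUE)
      mets <- data.frame(
        id = vapply(parts, `[`, "", 1),
        name = vapply(parts, `[`, "", 2),
        external = vapply(parts, `[`, "", 3) == "1",
        stringsAsFactors = FALSE)
    } else if (headers[s] == "reactions") {
      for (ln in seq_along(body)) {
        p <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
        if (length(p) < 2) stop("reaction row ", ln, " has no equation")
        eq <- tryCatch(parse_equation(p[2]),
                       error = function(e) stop("row ", ln, ": ", conditionMessage(e), call. = FALSE))
        rev <- if (length(p) >= 3 && nzchar(p[3])) p[3] == "1" else eq$reversible
        lbv <- if (length(p) >= 4 && nzchar(p[4])) as.numeric(p[4]) else NULL
        ubv <- if (length(p) >= 5 && nzchar(p[5])) as.numeric(p[5]) else NULL
        tgs <- if (length(p) >= 6 && nzchar(p[6])) strsplit(p[6], ",")[[1]] else character()
        rxns[[length(rxns) + 1]] <- list(id = p[1], stoich = eq$stoich,
                                         reversible = rev, lb = lbv, ub = ubv, tags = tgs)
      }
    }
  }
  if (is.null(mets)) stop("TSV model lacks a '# metabolites' section")
  network_model(mets, rxns, id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname model_io
#' @param model a [network_model].
#' @export
write_tsv_model <- function(model, path) {
  out <- c("# metabolites",
           paste(model$mets$id, model$mets$name,
                 as.integer(model$mets$external), sep = "\t"),
           "# reactions")
  for (k in seq_len(n_reactions(model))) {
    out <- c(out, paste(model$rxns$id[k], format_equation(model, k),
                        as.integer(model$rxns$reversible[k]),
                        model$rxns$lb[k], model$rxns$ub[k],
                        model$rxns$tags[k], sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

# "2 A + 3/14 B => C" -> list(stoich = c(A="-2", B="-3/14", C="1"), reversible)
parse_equation <- function(eq) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<=>" else "=>", fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("malformed equation: ", eq)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(character(0))
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    out <- character(0)
    for (t in terms) {
      bits <- strsplit(t, "\\s+")[[1]]
      if (length(bits) == 1) { cf <- "1"; met <- bits }
      else if (length(bits) == 2) { cf <- bits[1]; met <- bits[2] }
      else stop("malformed term '", t, "'")
      val <- tryCatch(as_rq(cf), error = function(e) NULL)
      if (is.null(val)) stop("non-numeric coefficient '", cf, "'")
      out[met] <- format(val * sign)
    }
    out
  }
  lhs <- parse_side(sides[1], rq(-1))
  rhs <- parse_side(sides[2], rq(1))
  both <- intersect(names(lhs), names(rhs))
  for (m in both) {   # metabolite on both sides: net coefficient
    rhs[m] <- format(as_rq(rhs[m]) + as_rq(lhs[m]))
    lhs <- lhs[names(lhs) != m]
  }
  st <- c(lhs, rhs)
  st <- st[st != "0"]
  list(stoich = st, reversible = rev)
}

format_equation <- function(model, k) {
  col <- model$stoich[, k]
  nz <- which(col$n != 0)
  lhs <- nz[col$n[nz] < 0]
  rhs <- nz[col$n[nz] > 0]
  fmt <- function(idx, sgn) {
    if (!length(idx)) return("")
    cf <- format(model$stoich[idx, k] * sgn)
    paste(ifelse(cf == "1", model$mets$id[idx],
                 paste(cf, model$mets$id[idx])), collapse = " + ")
  }
  arrow <- if (model$rxns$reversible[k]) "<=>" else "=>"
  paste(fmt(lhs, rq(-1)), arrow, fmt(rhs, rq(1)))
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
CYD_NS <- "https://cyanodesign.r/annotations"

#' @rdname model_io
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:cyd" = CYD_NS, level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "c", constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    xml2::xml_add_child(ls, "species",
      id = model$mets$id[i], name = model$mets$name[i], compartment = "c",
      boundaryCondition = tolower(model$mets$external[i]),
      hasOnlySubstanceUnits = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(n_reactions(model))) {
    rx <- xml2::xml_add_child(lr, "reaction",
      id = model$rxns$id[k],
      reversible = tolower(model$rxns$reversible[k]), fast = "false",
      "cyd:lb" = as.character(model$rxns$lb[k]),
      "cyd:ub" = as.character(model$rxns$ub[k]),
      "cyd:tags" = model$rxns$tags[k])
    col <- model$stoich[, k]
    nz <- which(col$n != 0)
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (i in nz) {
      parent <- if (col$n[i] < 0) lre else lpr
      xml2::xml_add_child(parent, "speciesReference",
        species = model$mets$id[i],
        stoichiometry = format(abs(col$n[i] / col$d[i]), digits = 15),
        constant = "true",
        "cyd:num" = as.character(abs(col$n[i])),
        "cyd:den" = as.character(col$d[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname model_io
#' @export
read_sbml <- function(path, external_suffix = c("_ex", "ext"),
                      external_ids = character()) {
  doc <- xml2::read_xml(path)   # malformed XML errors carry the line number
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML file declares no species")
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  bc <- xml2::xml_attr(sp, "boundaryCondition")
  external <- !is.na(bc) & bc == "true"
  if (all(is.na(bc))) {  # no flags anywhere: fall back to suffix rule
    sfx <- paste0("(", paste(external_suffix, collapse = "|"), ")$")
    external <- grepl(sfx, sid)
  }
  external <- external | sid %in% external_ids
  comp <- xml2::xml_attr(sp, "compartment")
  mets <- data.frame(id = sid, name = sname, external = external,
                     compartment = comp, stringsAsFactors = FALSE)

  # global fbc/flux parameters, if any
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- list()
  missing_sp <- character(0)
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    rev <- is.na(rev_attr) || rev_attr == "true"   # SBML default: reversible
    st <- character(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") rq(-1) else rq(1)
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        if (!met %in% sid) { missing_sp <- c(missing_sp, met); next }
        num <- xml2::xml_attr(ref, "num")
        den <- xml2::xml_attr(ref, "den")
        coef <- if (!is.na(num) && !is.na(den)) {
          rq(as.numeric(num), as.numeric(den))
        } else {
          sto <- xml2::xml_attr(ref, "stoichiometry")
          rationalize(if (is.na(sto)) 1 else as.numeric(sto))
        }
        prev <- if (met %in% names(st)) as_rq(st[[met]]) else rq(0)
        st[met] <- format(prev + coef * sgn)
      }
    }
    st <- st[st != "0"]
    lbv <- as.numeric(xml2::xml_attr(rx, "lb"))
    ubv <- as.numeric(xml2::xml_attr(rx, "ub"))
    if (is.na(lbv)) {  # kinetic-law parameter convention
      kl <- xml2::xml_find_all(rx, ".//parameter[@id='LOWER_BOUND']")
      if (length(kl)) lbv <- as.numeric(xml2::xml_attr(kl[[1]], "value"))
    }
    if (is.na(ubv)) {
      kl <- xml2::xml_find_all(rx, ".//parameter[@id='UPPER_BOUND']")
      if (length(kl)) ubv <- as.numeric(xml2::xml_attr(kl[[1]], "value"))
    }
    for (at in c("lowerFluxBound", "upperFluxBound")) {   # fbc package
      ref <- xml2::xml_attr(rx, at)
      if (!is.na(ref) && ref %in% names(parval)) {
        if (at == "lowerFluxBound" && is.na(lbv)) lbv <- parval[[ref]]
        if (at == "upperFluxBound" && is.na(ubv)) ubv <- parval[[ref]]
      }
    }
    tgs <- xml2::xml_attr(rx, "tags")
    tgs <- if (is.na(tgs) || !nzchar(tgs)) character() else strsplit(tgs, ",")[[1]]
    rxns[[length(rxns) + 1]] <- list(
      id = rid, stoich = st, reversible = rev,
      lb = if (is.na(lbv)) NULL else lbv,
      ub = if (is.na(ubv)) NULL else ubv, tags = tgs)
  }
  if (length(missing_sp))
    stop("reactions reference undeclared species: ",
         paste(unique(missing_sp), collapse = ", "))
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  network_model(mets, rxns, id = if (is.na(mid)) "sbml_model" else mid)
}

# continued-fraction rational approximation, exact for short decimals
rationalize <- function(x, max_den = 1e6, tol = 1e-9) {
  exact <- tryCatch(as_rq(x), error = function(e) NULL)
  if (!is.null(exact)) return(exact)
  a <- floor(x); h0 <- 1; h1 <- a; k0 <- 0; k1 <- 1; frac <- x - a
  while (abs(h1 / k1 - x) > tol * max(1, abs(x)) && k1 < max_den) {
    a <- floor(1 / frac)
    frac <- 1 / frac - a
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
  }
  rq(h1, k1)
}
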