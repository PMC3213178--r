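#' Read a reaction network from a file
#'
#' Two formats are supported. The plain-text format has one reaction per
#' line, `"R1: A + 2*B -> C ; k=0.1"`, with `<->` marking a reversible
#' reaction whose constants are given as `kf=, kr=`; an empty side is
#' written `0` (source/sink). Species initial amounts are declared on
#' `init` lines, `"init: A = 1.5"` (species not declared default to 0; any
#' species appearing only in `init` lines is kept, so isolated species are
#' representable). `#` starts a comment. The SBML reader accepts a minimal
#' Level-2 subset: `listOfSpecies`, `listOfReactions` with reactant/product
#' stoichiometries, a `reversible` attribute, and a `kineticLaw` that is a
#' single constant (mass-action constant; reversible laws carry two).
#' Anything outside the subset (events, rules, function definitions,
#' non-mass-action laws) raises an "unsupported construct" error rather
#' than being skipped.
#'
#' @param path file path
#' @param format `"text"` or `"sbml"`; guessed from the extension by default
#' @return a [rxn_network()] with species and reactions in file order
#' @export
parse_network <- function(path, format = c("auto", "text", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "text"
  }
  switch(format, text = parse_network_text(path), sbml = parse_network_sbml(path))
}

parse_side <- function(side, line) {
  side <- trimws(side)
  if (side == "" || side == "0") return(setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  coef <- rep(1, length(terms))
  sp <- terms
  has_star <- grepl("*", terms, fixed = TRUE)
  for (i in which(has_star)) {
    parts <- trimws(strsplit(terms[i], "*", fixed = TRUE)[[1]])
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[1])))) {
      abort(paste0("cannot parse reaction term '", terms[i], "' in line: ", line))
    }
    coef[i] <- as.numeric(parts[1])
    sp[i] <- parts[2]
  }
  if (any(sp == "") || any(coef < 1) || any(coef != round(coef))) {
    abort(paste0("bad stoichiometry in line: ", line))
  }
  tapply(coef, sp, sum)[unique(sp)]
}

parse_network_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  inits <- list()
  rxn_rows <- list()
  order_seen <- character(0)
  for (line in lines) {
    if (grepl("^init\\s*:", line)) {
      body <- sub("^init\\s*:", "", line)
      parts <- trimws(strsplit(body, "=", fixed = TRUE)[[1]])
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) {
        abort(paste0("cannot parse init line: ", line))
      }
      inits[[parts[1]]] <- as.numeric(parts[2])
      if (!parts[1] %in% order_seen) order_seen <- c(order_seen, parts[1])
      next
    }
    m <- regmatches(line, regexec(
      "^([^:]+):\\s*(.*?)\\s*(<->|->)\\s*(.*?)\\s*;\\s*(.*)$", line,
      perl = TRUE))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse reaction line: ", line))
    id <- trimws(m[2]); lhs <- m[3]; arrow <- m[4]; rhs <- m[5]; kpart <- m[6]
    reactants <- parse_side(lhs, line)
    products <- parse_side(rhs, line)
    kv <- strsplit(kpart, ",")[[1]]
    kv <- do.call(rbind, lapply(kv, function(s) trimws(strsplit(s, "=")[[1]])))
    keys <- setNames(as.numeric(kv[, 2]), kv[, 1])
    if (arrow == "<->") {
      if (!all(c("kf", "kr") %in% names(keys))) {
        abort(paste0("reversible reaction needs kf= and kr= : ", line))
      }
      row <- tibble(id = id, rate_constant = keys[["kf"]],
                    rate_constant_rev = keys[["kr"]], reversible = TRUE)
    } else {
      if (!"k" %in% names(keys)) abort(paste0("reaction needs k= : ", line))
      row <- tibble(id = id, rate_constant = keys[["k"]],
                    rate_constant_rev = NA_real_, reversible = FALSE)
    }
    row$reactants <- list(reactants)
    row$products <- list(products)
    rxn_rows[[length(rxn_rows) + 1L]] <- row
    for (s in c(names(reactants), names(products))) {
      if (!s %in% order_seen) order_seen <- c(order_seen, s)
    }
  }
  if (!length(rxn_rows)) abort(paste0("no reactions found in ", path))
  species <- tibble(
    id = order_seen,
    initial_amount = unname(vapply(order_seen,
                                   function(s) inits[[s]] %||% 0, numeric(1)))
  )
  rxn_network(species, dplyr::bind_rows(rxn_rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reaction network to a file
#'
#' Inverse of [parse_network()]; round-tripping preserves species and
#' reaction order, stoichiometry, rate constants and initial amounts.
#'
#' @param net a `rxn_network`
#' @param path output path
#' @param format `"text"` or `"sbml"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("text", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(write_network_sbml(net, path))
  fmt_side <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v > 1, paste0(v, "*", names(v)), names(v)), collapse = " + ")
  }
  lines <- vapply(seq_len(nrow(net$reactions)), function(j) {
    r <- net$reactions[j, ]
    if (r$reversible) {
      sprintf("%s: %s <-> %s ; kf=%.17g, kr=%.17g", r$id,
              fmt_side(r$reactants[[1]]), fmt_side(r$products[[1]]),
              r$rate_constant, r$rate_constant_rev)
    } else {
      sprintf("%s: %s -> %s ; k=%.17g", r$id,
              fmt_side(r$reactants[[1]]), fmt_side(r$products[[1]]),
              r$rate_constant)
    }
  }, character(1))
  init_lines <- sprintf("init: %s = %.17g", net$species$id,
                        net$species$initial_amount)
  writeLines(c(init_lines, lines), path)
  invisible(path)
}

#' Export species and reaction summary tables
#'
#' @param net a `rxn_network`
#' @param dir directory for `species.csv` and `reactions.csv`
#' @return the two file paths, invisibly
#' @export
export_network_tables <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_path <- file.path(dir, "species.csv")
  rx_path <- file.path(dir, "reactions.csv")
  write.csv(net$species, sp_path, row.names = FALSE)
  write.csv(as.data.frame(tidy(net)), rx_path, row.names = FALSE)
  invisible(c(sp_path, rx_path))
}
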