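# Plain-text and JSON serialization of mechanisms.  The text grammar is a
# KPP-like line format:
#
#   # comment / blank lines ignored
#   variant catalytic-111
#   fast_kr 1000
#   species Fe(SO4)2- : init=0 : groups iron=1 sulfate=2
#   R14_Fe3+: Fe3+ + AH2 + O2 -> Fe3+ + DHA + H2O2 : k=5.7e4 : \
#       orders Fe3+=1 AH2=1 O2=1 : base R14 : tags catalytic
#
# Reaction fields after the equation are ':'-separated clauses:
#   k=<number>            rate constant (required)
#   orders A=1 B=0.5      kinetic orders (default: reactant stoichiometry)
#   pool A,B exp=-0.5     pooled-concentration factor (sum(A,B)^exp)
#   base <id>             table-row id for lumped/split reactions
#   tags a,b              classification tags
#   kspec <name>          condition-dependent constant (R45, R20)
#   note <text>           free text (no colons)

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a mechanism to its plain-text format
#'
#' @param mech An `aa_mechanism`.
#' @param path Optional file path; if `NULL` the text is returned invisibly.
#' @return Character vector of lines (invisibly if written to `path`).
#' @seealso [parse_mechanism_file()]
#' @export
write_mechanism_file <- function(mech, path = NULL) {
  lines <- c("# ascorbox mechanism", paste("variant", mech$variant),
             paste("fast_kr", .fmt_num(mech$fast_kr)))
  moieties <- aa_moiety_names()
  for (i in seq_len(nrow(mech$species))) {
    row <- mech$species[i, ]
    g <- unlist(row[moieties])
    g <- g[g != 0]
    gtxt <- if (length(g)) paste(" : groups",
                                 paste(names(g), unname(g), sep = "=",
                                       collapse = " ")) else ""
    lines <- c(lines, sprintf("species %s : init=%s%s", row$name,
                              .fmt_num(row$default_initial), gtxt))
  }
  for (r in mech$reactions) {
    clauses <- c(
      sprintf("k=%s", .fmt_num(r$k)),
      if (length(r$orders))
        paste("orders", paste(names(r$orders), .fmt_num(unname(r$orders)),
                              sep = "=", collapse = " ")),
      if (!is.null(r$pool))
        sprintf("pool %s exp=%s", paste(r$pool, collapse = ","),
                .fmt_num(r$pool_exp)),
      if (r$base_id != r$id) paste("base", r$base_id),
      if (length(r$tags)) paste("tags", paste(r$tags, collapse = ",")),
      if (r$kspec != "fixed") paste("kspec", r$kspec),
      if (nzchar(r$note)) paste("note", gsub(":", ";", r$note, fixed = TRUE))
    )
    lines <- c(lines, sprintf("%s: %s -> %s : %s", r$id,
                              .format_side(r$reactants),
                              .format_side(r$products),
                              paste(clauses, collapse = " : ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.parse_kv <- function(text, what, line_no) {
  parts <- strsplit(trimws(text), "\\s+")[[1]]
  out <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[2]))))
      stop(sprintf("line %d: malformed %s entry '%s'", line_no, what, p))
    out[kv[1]] <- as.numeric(kv[2])
  }
  out
}

#' Parse a mechanism from its plain-text format
#'
#' Inverse of [write_mechanism_file()]: `parse(write(m))` reproduces `m`
#' and `write(parse(text))` reproduces canonical text.  Species may be
#' declared with `species` lines; when a file contains no species block,
#' the species are inferred from the reactions (with zero initials and no
#' moiety groups).  Undeclared species (when a block is present), negative
#' rate constants and malformed stoichiometry are rejected with the
#' offending line number.
#'
#' @param text Character vector of lines, or a length-1 path to a file.
#' @return An `aa_mechanism`.
#' @export
parse_mechanism_file <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  variant <- "catalytic-111"; fast_kr <- 1e10
  sp_rows <- list(); reactions <- list()
  moieties <- aa_moiety_names()
  has_species_block <- FALSE

  for (i in seq_along(text)) {
    ln <- trimws(text[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "variant ")) { variant <- trimws(sub("^variant", "", ln)); next }
    if (startsWith(ln, "fast_kr ")) { fast_kr <- as.numeric(sub("^fast_kr", "", ln)); next }
    if (startsWith(ln, "species ")) {
      has_species_block <- TRUE
      clauses <- strsplit(sub("^species\\s+", "", ln), " : ", fixed = TRUE)[[1]]
      nm <- trimws(clauses[1])
      init <- 0; groups <- numeric(0)
      for (cl in clauses[-1]) {
        cl <- trimws(cl)
        if (startsWith(cl, "init=")) {
          init <- suppressWarnings(as.numeric(sub("^init=", "", cl)))
          if (is.na(init)) stop(sprintf("line %d: bad species initial", i))
        } else if (startsWith(cl, "groups ")) {
          groups <- .parse_kv(sub("^groups", "", cl), "group", i)
          bad <- setdiff(names(groups), moieties)
          if (length(bad)) stop(sprintf("line %d: unknown moiety group %s",
                                        i, paste(bad, collapse = ",")))
        }
      }
      sp_rows[[length(sp_rows) + 1L]] <- list(name = nm, init = init,
                                              groups = groups)
      next
    }
    # reaction line
    main <- strsplit(ln, " : ", fixed = TRUE)[[1]]
    head_part <- main[1]
    ci <- regexpr(":", head_part, fixed = TRUE)
    if (ci < 0) stop(sprintf("line %d: expected 'id: equation'", i))
    id <- trimws(substr(head_part, 1, ci - 1))
    eq <- trimws(substr(head_part, ci + 1, nchar(head_part)))
    if (!grepl("->", eq, fixed = TRUE))
      stop(sprintf("line %d: equation missing '->'", i))
    pe <- tryCatch(.parse_equation(eq),
                   error = function(e) stop(sprintf("line %d: %s", i,
                                                    conditionMessage(e))))
    if ((length(pe$reactants) && any(!is.finite(pe$reactants) | pe$reactants <= 0)) ||
        (length(pe$products) && any(!is.finite(pe$products) | pe$products <= 0)))
      stop(sprintf("line %d: malformed stoichiometry", i))
    k <- NA_real_; orders <- NULL; pool <- NULL; pool_exp <- 0
    base_id <- id; tags <- character(0); kspec <- "fixed"; note <- ""
    for (cl in main[-1]) {
      cl <- trimws(cl)
      if (grepl("^k\\s*=", cl)) {
        k <- suppressWarnings(as.numeric(sub("^k\\s*=\\s*", "", cl)))
        if (is.na(k)) stop(sprintf("line %d: bad rate constant", i))
      } else if (startsWith(cl, "orders")) {
        orders <- .parse_kv(sub("^orders", "", cl), "order", i)
      } else if (startsWith(cl, "pool")) {
        m <- regmatches(cl, regexec("^pool\\s+(\\S+)\\s+exp=(\\S+)$", cl))[[1]]
        if (length(m) != 3) stop(sprintf("line %d: malformed pool clause", i))
        pool <- strsplit(m[2], ",", fixed = TRUE)[[1]]
        pool_exp <- as.numeric(m[3])
      } else if (startsWith(cl, "base")) {
        base_id <- trimws(sub("^base", "", cl))
      } else if (startsWith(cl, "tags")) {
        tags <- strsplit(trimws(sub("^tags", "", cl)), ",", fixed = TRUE)[[1]]
      } else if (startsWith(cl, "kspec")) {
        kspec <- trimws(sub("^kspec", "", cl))
      } else if (startsWith(cl, "note")) {
        note <- trimws(sub("^note", "", cl))
      } else {
        stop(sprintf("line %d: unknown clause '%s'", i, cl))
      }
    }
    if (is.na(k)) stop(sprintf("line %d: missing rate constant", i))
    if (k < 0) stop(sprintf("line %d: negative rate constant", i))
    if (is.null(orders)) {
      orders <- pe$reactants
      orders[names(orders) == "H2O"] <- 0
      orders <- orders[orders > 0]
    }
    reactions[[length(reactions) + 1L]] <-
      .new_reaction(id, base_id, pe$reactants, pe$products, orders, k,
                    kspec = kspec, pool = pool, pool_exp = pool_exp,
                    tags = tags, note = note)
  }

  if (has_species_block) {
    species <- data.frame(
      name = vapply(sp_rows, `[[`, character(1), "name"),
      default_initial = vapply(sp_rows, `[[`, numeric(1), "init"),
      stringsAsFactors = FALSE
    )
    for (m in moieties) {
      species[[m]] <- vapply(sp_rows, function(s) {
        if (m %in% names(s$groups)) s$groups[[m]] else 0
      }, numeric(1))
    }
  } else {
    nm <- unique(unlist(lapply(reactions, function(r)
      c(names(r$reactants), names(r$products), names(r$orders), r$pool))))
    if (is.null(nm)) nm <- character(0)
    species <- data.frame(name = nm, default_initial = rep(0, length(nm)),
                          stringsAsFactors = FALSE)
    for (m in moieties) species[[m]] <- rep(0, nrow(species))
  }
  # undeclared species (with a declared block) are reported per line by
  # .new_mechanism's collective check; locate the first offender for a
  # line-numbered message
  if (has_species_block) {
    for (j in seq_along(reactions)) {
      r <- reactions[[j]]
      unknown <- setdiff(c(names(r$reactants), names(r$products)), species$name)
      if (length(unknown))
        stop(sprintf("reaction %s: undeclared species %s", r$id,
                     paste(unknown, collapse = ", ")))
    }
  }
  .new_mechanism(species, reactions, variant, fast_kr)
}

#' Serialize a mechanism to JSON
#' @param mech An `aa_mechanism`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written).
#' @export
mechanism_to_json <- function(mech, path = NULL) {
  payload <- list(
    variant = mech$variant,
    fast_kr = mech$fast_kr,
    species = mech$species,
    reactions = lapply(mech$reactions, function(r) {
      list(id = r$id, base_id = r$base_id,
           reactants = as.list(r$reactants), products = as.list(r$products),
           orders = as.list(r$orders), k = r$k, kspec = r$kspec,
           pool = r$pool, pool_exp = r$pool_exp, tags = as.list(r$tags),
           note = r$note)
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a mechanism from its JSON serialization
#' @param json JSON string or path.
#' @return An `aa_mechanism`.
#' @export
mechanism_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  species <- do.call(rbind, lapply(x$species, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  reactions <- lapply(x$reactions, function(r) {
    .new_reaction(r$id, r$base_id,
                  unlist(r$reactants) %||% setNames(numeric(0), character(0)),
                  unlist(r$products) %||% setNames(numeric(0), character(0)),
                  unlist(r$orders) %||% setNames(numeric(0), character(0)),
                  r$k, kspec = r$kspec,
                  pool = if (is.null(r$pool)) NULL else unlist(r$pool),
                  pool_exp = r$pool_exp %||% 0,
                  tags = as.character(unlist(r$tags)), note = r$note %||% "")
  })
  .new_mechanism(species, reactions, x$variant, x$fast_kr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
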