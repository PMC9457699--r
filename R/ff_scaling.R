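# ---- constructors -----------------------------------------------------------

#' Per-type Lennard-Jones parameters (CHARMM sign convention)
#'
#' CHARMM parameter files store the well depth epsilon as a non-positive
#' number; that convention is retained here and magnitudes are used in
#' arithmetic.
#'
#' @param name atom-type token (<= 6 characters, stored uppercase)
#' @param epsilon LJ well depth, kcal/mol, must be <= 0
#' @param rmin_half Rmin/2, Angstrom, must be > 0
#' @param epsilon14,rmin14_half optional 1-4 overrides (never scaled)
#' @return an object of class \code{atom_type_lj}
#' @export
atom_type_lj <- function(name, epsilon, rmin_half,
                         epsilon14 = NA_real_, rmin14_half = NA_real_) {
  name <- toupper(as.character(name))
  if (nchar(name) < 1L || nchar(name) > 6L)
    stop("atom-type token must be 1..6 characters: ", name)
  if (!is.finite(epsilon) || epsilon > 0)
    stop("epsilon must be finite and <= 0 (CHARMM convention), got ", epsilon)
  if (!is.finite(rmin_half) || rmin_half <= 0)
    stop("rmin_half must be positive, got ", rmin_half)
  structure(list(name = name, epsilon = epsilon, rmin_half = rmin_half,
                 epsilon14 = epsilon14, rmin14_half = rmin14_half),
            class = "atom_type_lj")
}

#' Pairwise Lennard-Jones cross term (an NBFIX line)
#'
#' @param type_i,type_j atom-type tokens; the pair is unordered and stored
#'   sorted so that (i, j) and (j, i) compare equal
#' @param epsilon_ij well depth, kcal/mol, <= 0
#' @param rmin_ij minimum-energy distance, Angstrom (sum form, not half)
#' @return an object of class \code{pair_lj}
#' @export
pair_lj <- function(type_i, type_j, epsilon_ij, rmin_ij) {
  if (!is.finite(epsilon_ij) || epsilon_ij > 0)
    stop("epsilon_ij must be <= 0, got ", epsilon_ij)
  if (!is.finite(rmin_ij) || rmin_ij <= 0)
    stop("rmin_ij must be positive, got ", rmin_ij)
  toks <- sort(toupper(c(type_i, type_j)))
  structure(list(type_i = toks[1L], type_j = toks[2L],
                 epsilon_ij = epsilon_ij, rmin_ij = rmin_ij),
            class = "pair_lj")
}

# ---- parsing ----------------------------------------------------------------

#' Parse a CHARMM-dialect nonbonded parameter text
#'
#' Reads the NONBONDED section (per-type LJ lines, optional 1-4 columns) and
#' any NBFIX section of a CHARMM .prm/.str dialect.  Comments start with
#' \code{!}; continuation markers and HBOND-era columns are tolerated;
#' unknown sections are skipped with a warning.
#'
#' @param text character scalar or vector of lines
#' @return list with \code{types} (named list of \code{atom_type_lj}) and
#'   \code{nbfix} (list of \code{pair_lj})
#' @export
parse_charmm_nonbonded <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else as.character(text)
  raw <- lines
  # strip comments and trailing continuation markers
  lines <- sub("!.*$", "", lines)
  lines <- sub("-\\s*$", "", lines)
  lines <- trimws(lines)

  section <- "none"
  types <- list()
  nbfix <- list()
  seen_nonbonded <- FALSE
  section_kw <- c("NONBONDED", "NBFIX", "BONDS", "ANGLES", "DIHEDRALS",
                  "IMPROPERS", "IMPROPER", "CMAP", "ATOMS", "HBOND", "END",
                  "RETURN")

  num_or_stop <- function(tok, lineno) {
    x <- suppressWarnings(as.numeric(tok))
    if (is.na(x))
      stop("malformed numeric field '", tok, "' at line ", lineno, ": ",
           raw[lineno])
    x
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    kw <- toupper(toks[1L])
    if (kw %in% section_kw) {
      if (kw == "NONBONDED") { section <- "nonbonded"; seen_nonbonded <- TRUE }
      else if (kw == "NBFIX") section <- "nbfix"
      else if (kw %in% c("END", "RETURN")) section <- "none"
      else {
        if (!kw %in% c("HBOND")) # HBOND often follows NONBONDED; silent-ish
          warning("skipping unknown section '", kw, "' at line ", i)
        section <- "skip"
      }
      next
    }
    if (section == "nonbonded") {
      # TYPE ignored epsilon Rmin/2 [ignored eps14 Rmin14/2]
      if (length(toks) < 4L) next  # option continuation lines (cutnb etc.)
      if (!grepl("^[A-Za-z]", toks[1L])) next
      # NONBONDED option lines (cutoffs, dielectric flags) are not types
      opts <- c("nbxmod", "cutnb", "ctofnb", "ctonnb", "eps", "e14fac",
                "wmin", "atom", "vatom", "cdiel", "rdiel", "cdie", "rdie",
                "switch", "vswitch", "fswitch", "vfswitch", "shift",
                "vshift", "fshift", "vdistance", "group", "bycb", "bygr",
                "inbfrq", "imgfrq", "nbscale", "lrc", "soft")
      if (tolower(toks[1L]) %in% opts) next
      nm <- toupper(toks[1L])
      eps <- num_or_stop(toks[3L], i)
      rmh <- num_or_stop(toks[4L], i)
      e14 <- if (length(toks) >= 7L) num_or_stop(toks[6L], i) else NA_real_
      r14 <- if (length(toks) >= 7L) num_or_stop(toks[7L], i) else NA_real_
      if (!is.null(types[[nm]]))
        stop("duplicate atom-type token '", nm, "' at line ", i)
      types[[nm]] <- atom_type_lj(nm, eps, rmh, e14, r14)
    } else if (section == "nbfix") {
      if (length(toks) < 4L)
        stop("malformed NBFIX line at line ", i, ": ", raw[i])
      p <- pair_lj(toks[1L], toks[2L],
                   num_or_stop(toks[3L], i), num_or_stop(toks[4L], i))
      key <- paste(p$type_i, p$type_j)
      if (!is.null(nbfix[[key]]))
        warning("duplicate NBFIX pair ", key, " at line ", i, "; last wins")
      nbfix[[key]] <- p
    }
  }
  if (!seen_nonbonded && length(nbfix) == 0L)
    stop("no NONBONDED or NBFIX section found")
  list(types = types, nbfix = unname(nbfix))
}

# ---- combination / scaling --------------------------------------------------

#' Lorentz-Berthelot cross term for two LJ types (CHARMM rules)
#'
#' epsilon_ij = -sqrt(|eps_i| |eps_j|), rmin_ij = rmin_half_i + rmin_half_j.
#'
#' @param a,b \code{atom_type_lj} objects
#' @return a \code{pair_lj}
#' @export
combine_lj <- function(a, b) {
  stopifnot(inherits(a, "atom_type_lj"), inherits(b, "atom_type_lj"))
  pair_lj(a$name, b$name,
          -sqrt(abs(a$epsilon) * abs(b$epsilon)),
          a$rmin_half + b$rmin_half)
}

#' Scale the well depth of a pair by lambda
#'
#' Multiplies |epsilon_ij| by \code{lam} keeping the CHARMM sign; rmin is
#' untouched.
#'
#' @param p a \code{pair_lj}
#' @param lam scaling parameter lambda, > 0
#' @return scaled \code{pair_lj}
#' @export
scale_pair <- function(p, lam) {
  stopifnot(inherits(p, "pair_lj"))
  if (!is.finite(lam) || lam <= 0) stop("lambda must be > 0, got ", lam)
  p$epsilon_ij <- p$epsilon_ij * lam
  p
}

#' Build a lambda-scaled protein-water NBFIX table
#'
#' Forms every (protein type, water type) cross term by the combination
#' rules, scales the well depth by lambda, and returns the table sorted
#' lexicographically by pair.  Protein-protein and water-water pairs are
#' never emitted; 1-4 overrides are never scaled.
#'
#' @param types named list of \code{atom_type_lj} (as from
#'   \code{parse_charmm_nonbonded()$types})
#' @param protein_types character vector of protein tokens, or NULL for
#'   "every parsed type not in water_types"
#' @param water_types character vector of water tokens (default the modified
#'   TIP3P \code{c("OT","HT")}, which carries LJ on hydrogen)
#' @param lam scaling parameter lambda (> 0); 1.00 reproduces the plain
#'   combination rules exactly
#' @param provenance free-text note stored with the table
#' @return object of class \code{nbfix_table}
#' @export
generate_nbfix <- function(types, protein_types = NULL,
                           water_types = c("OT", "HT"), lam = 1.03,
                           provenance = "") {
  if (!is.finite(lam) || lam <= 0) stop("lambda must be > 0")
  all_tok <- toupper(names(types))
  water_types <- toupper(water_types)
  if (is.null(protein_types)) {
    protein_types <- setdiff(all_tok, water_types)
  } else protein_types <- toupper(protein_types)
  if (length(intersect(protein_types, water_types)))
    stop("protein and water type sets overlap: ",
         paste(intersect(protein_types, water_types), collapse = ", "))
  missing <- setdiff(c(protein_types, water_types), all_tok)
  if (length(missing))
    stop("unresolvable atom types: ", paste(missing, collapse = ", "))
  if (length(water_types) == 0L) stop("water type set is empty")
  if (length(protein_types) == 0L) stop("protein type set is empty")

  grid <- expand.grid(p = protein_types, w = water_types,
                      stringsAsFactors = FALSE)
  entries <- lapply(seq_len(nrow(grid)), function(i)
    scale_pair(combine_lj(types[[grid$p[i]]], types[[grid$w[i]]]), lam))
  key <- vapply(entries, function(p) paste(p$type_i, p$type_j), "")
  entries <- entries[order(key)]
  structure(list(entries = entries, lam = lam,
                 protein_types = sort(protein_types),
                 water_types = sort(water_types),
                 provenance = provenance),
            class = "nbfix_table")
}

#' @export
print.nbfix_table <- function(x, ...) {
  cat(sprintf("NBFIX table: lambda = %.4f, %d pairs (%d protein x %d water types)\n",
              x$lam, length(x$entries), length(x$protein_types),
              length(x$water_types)))
  invisible(x)
}

#' Convert an NBFIX table to a data frame
#'
#' @param x \code{nbfix_table}
#' @param ... unused
#' @return data.frame with type_i, type_j, epsilon_ij, rmin_ij
#' @export
as.data.frame.nbfix_table <- function(x, ...) {
  data.frame(
    type_i = vapply(x$entries, `[[`, "", "type_i"),
    type_j = vapply(x$entries, `[[`, "", "type_j"),
    epsilon_ij = vapply(x$entries, `[[`, 0, "epsilon_ij"),
    rmin_ij = vapply(x$entries, `[[`, 0, "rmin_ij"),
    stringsAsFactors = FALSE)
}

#' Write an NBFIX table as a CHARMM stream
#'
#' Output is byte-stable across runs: fixed decimal formatting (epsilon to 6
#' decimals, rmin to 4), lexicographic pair order, a date-free provenance
#' header, terminated by \code{END}.
#'
#' @param t \code{nbfix_table}
#' @param file optional path; when NULL the text is returned invisibly
#' @return character vector of lines (invisibly when \code{file} given)
#' @export
write_nbfix_stream <- function(t, file = NULL) {
  stopifnot(inherits(t, "nbfix_table"))
  if (length(t$entries) == 0L) stop("refusing to write an empty NBFIX table")
  header <- c(
    sprintf("* protein-water LJ cross terms, lambda = %.4f", t$lam),
    if (nzchar(t$provenance)) paste0("* ", t$provenance),
    "*",
    "")
  body <- vapply(t$entries, function(p)
    sprintf("%-6s %-6s %12.6f %10.4f", p$type_i, p$type_j,
            p$epsilon_ij, p$rmin_ij), "")
  out <- c(header, "NBFIX", body, "", "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
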