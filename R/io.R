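#' Read and write structure files
#'
#' Multi-conformer XYZ and SDF V2000 input/output. SDF round trips
#' preserve elements, coordinates (to the 1e-4 Angstrom precision of
#' the format), the full bond list, and - through `MACROCONF_*` data
#' fields - the bond-order dialect (single/double/ester/coordination),
#' atom labels and torsion labels. XYZ carries elements and
#' coordinates only.
#'
#' @param path File path.
#' @param format "xyz", "sdf", or "auto" (from the file extension).
#' @return `read_structure`: list with `molecule` and `conformers`
#'   (list of [conformer()]).
#' @export
read_structure <- function(path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", sdf = "sdf", sd = "sdf",
                     mc_stop(sprintf("cannot infer format of '%s'", path),
                             "macroconf_parse_error"))
  }
  if (format == "xyz") read_xyz(path) else read_sdf(path)
}

#' @rdname read_structure
#' @param mol A `macro_molecule`.
#' @param conformers A conformer or list of conformers.
#' @export
write_structure <- function(mol, conformers, path,
                            format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", sdf = "sdf", sd = "sdf",
                     mc_stop(sprintf("cannot infer format of '%s'", path),
                             "macroconf_parse_error"))
  }
  if (is.matrix(conformers)) conformers <- list(conformers)
  if (format == "xyz") write_xyz(mol, conformers, path)
  else write_sdf(mol, conformers, path)
  invisible(path)
}

parse_fail <- function(path, line, msg) {
  mc_stop(sprintf("%s:%d: %s", path, line, msg), "macroconf_parse_error")
}

read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) parse_fail(path, i, "expected an atom count")
    if (i + 1L + nat > length(lines)) {
      parse_fail(path, length(lines), "truncated XYZ frame")
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    f <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(f, `[`, character(1), 1)
    xyz <- t(vapply(f, function(v) {
      if (length(v) < 4) return(c(NA_real_, NA_real_, NA_real_))
      suppressWarnings(as.numeric(v[2:4]))
    }, numeric(3)))
    if (any(is.na(xyz))) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      parse_fail(path, i + 1L + bad, "malformed XYZ atom line")
    }
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el)) {
      parse_fail(path, i, "XYZ frames have inconsistent elements")
    }
    frames[[length(frames) + 1L]] <- conformer(xyz)
    i <- i + 2L + nat
  }
  if (!length(frames)) parse_fail(path, 1L, "no XYZ frames found")
  atoms <- data.frame(element = elements,
                      label = paste0(elements, seq_along(elements)),
                      ring_index = NA, stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  list(molecule = macro_molecule(basename(path), atoms, bonds),
       conformers = frames)
}

write_xyz <- function(mol, conformers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    cf <- as.matrix(cf)
    writeLines(as.character(nrow(cf)), con)
    e <- conf_energy(cf)
    writeLines(sprintf("%s%s", mol$name,
                       if (!is.null(e) && is.finite(e))
                         sprintf(" E=%.6f", e) else ""), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f",
                       mol$atoms$element, cf[, 1], cf[, 2], cf[, 3]), con)
  }
}

sdf_order_code <- c(single = 1L, double = 2L, ester = 1L, coordination = 8L)

write_sdf <- function(mol, conformers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  for (ci in seq_along(conformers)) {
    cf <- as.matrix(conformers[[ci]])
    writeLines(c(mol$name, "  macroconf", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nat, nb),
               con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       cf[, 1], cf[, 2], cf[, 3], mol$atoms$element), con)
    if (nb > 0) {
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                         sdf_order_code[mol$bonds$order]), con)
    }
    writeLines("M  END", con)
    writeLines(c(">  <MACROCONF_BOND_ORDERS>",
                 paste(mol$bonds$order, collapse = " "), ""), con)
    writeLines(c(">  <MACROCONF_ATOM_LABELS>",
                 paste(mol$atoms$label, collapse = " "), ""), con)
    ri <- mol$atoms$ring_index
    writeLines(c(">  <MACROCONF_RING_INDEX>",
                 paste(ifelse(is.na(ri), ".", ri), collapse = " "), ""), con)
    if (length(mol$torsion_labels)) {
      writeLines(c(">  <MACROCONF_TORSIONS>",
                   paste(vapply(names(mol$torsion_labels), function(nm) {
                     paste(nm, paste(mol$torsion_labels[[nm]],
                                     collapse = " "))
                   }, character(1)), collapse = "; "), ""), con)
    }
    if (!is.null(mol$closure_bond)) {
      writeLines(c(">  <MACROCONF_CLOSURE_BOND>",
                   paste(mol$closure_bond, collapse = " "), ""), con)
    }
    e <- conf_energy(conformers[[ci]])
    if (!is.null(e) && is.finite(e)) {
      writeLines(c(">  <ENERGY_KCAL_MOL>", sprintf("%.6f", e), ""), con)
    }
    writeLines("$$$$", con)
  }
}

read_sdf <- function(path) {
  lines <- readLines(path)
  i <- 1L
  mols <- list()
  confs <- list()
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i])) && i + 3 > n) break
    if (i + 3 > n) parse_fail(path, i, "truncated SDF record header")
    name <- lines[i]
    counts_line <- i + 3L
    nat <- suppressWarnings(as.integer(substr(lines[counts_line], 1, 3)))
    nb <- suppressWarnings(as.integer(substr(lines[counts_line], 4, 6)))
    if (is.na(nat) || is.na(nb)) {
      parse_fail(path, counts_line, "malformed counts line")
    }
    if (counts_line + nat + nb > n) {
      parse_fail(path, n, "truncated atom/bond block")
    }
    ablock <- lines[(counts_line + 1L):(counts_line + nat)]
    xyz <- matrix(NA_real_, nat, 3)
    el <- character(nat)
    for (a in seq_len(nat)) {
      ln <- ablock[a]
      xyz[a, ] <- suppressWarnings(as.numeric(c(substr(ln, 1, 10),
                                                substr(ln, 11, 20),
                                                substr(ln, 21, 30))))
      el[a] <- trimws(substr(ln, 31, 34))
      if (any(is.na(xyz[a, ])) || !nzchar(el[a])) {
        parse_fail(path, counts_line + a, "malformed atom line")
      }
    }
    bi <- integer(nb); bj <- integer(nb); bt <- integer(nb)
    for (r in seq_len(nb)) {
      ln <- lines[counts_line + nat + r]
      bi[r] <- suppressWarnings(as.integer(substr(ln, 1, 3)))
      bj[r] <- suppressWarnings(as.integer(substr(ln, 4, 6)))
      bt[r] <- suppressWarnings(as.integer(substr(ln, 7, 9)))
      if (is.na(bi[r]) || is.na(bj[r]) || is.na(bt[r]) ||
          bi[r] < 1 || bj[r] < 1 || bi[r] > nat || bj[r] > nat) {
        parse_fail(path, counts_line + nat + r, "malformed bond line")
      }
    }
    # find M END then data fields until $$$$
    j <- counts_line + nat + nb + 1L
    while (j <= n && !startsWith(lines[j], "M  END")) j <- j + 1L
    if (j > n) parse_fail(path, n, "missing 'M  END'")
    fields <- list()
    j <- j + 1L
    while (j <= n && !startsWith(lines[j], "$$$$")) {
      m <- regmatches(lines[j], regexec("^>.*<([^>]+)>", lines[j]))[[1]]
      if (length(m) == 2 && j + 1L <= n) {
        fields[[m[2]]] <- lines[j + 1L]
        j <- j + 2L
      } else {
        j <- j + 1L
      }
    }
    i <- j + 1L

    orders <- if (!is.null(fields$MACROCONF_BOND_ORDERS)) {
      strsplit(trimws(fields$MACROCONF_BOND_ORDERS), "[[:space:]]+")[[1]]
    } else {
      c("1" = "single", "2" = "double", "3" = "single",
        "8" = "coordination")[as.character(bt)]
    }
    if (length(orders) != nb || any(is.na(orders))) {
      parse_fail(path, counts_line, "unsupported bond types")
    }
    labels <- if (!is.null(fields$MACROCONF_ATOM_LABELS)) {
      strsplit(trimws(fields$MACROCONF_ATOM_LABELS), "[[:space:]]+")[[1]]
    } else paste0(el, seq_len(nat))
    ring_index <- if (!is.null(fields$MACROCONF_RING_INDEX)) {
      suppressWarnings(as.integer(
        strsplit(trimws(fields$MACROCONF_RING_INDEX), "[[:space:]]+")[[1]]))
    } else rep(NA_integer_, nat)
    torsion_labels <- list()
    if (!is.null(fields$MACROCONF_TORSIONS)) {
      for (part in strsplit(fields$MACROCONF_TORSIONS, ";")[[1]]) {
        v <- strsplit(trimws(part), "[[:space:]]+")[[1]]
        torsion_labels[[v[1]]] <- as.integer(v[-1])
      }
    }
    closure <- if (!is.null(fields$MACROCONF_CLOSURE_BOND)) {
      as.integer(strsplit(trimws(fields$MACROCONF_CLOSURE_BOND),
                          "[[:space:]]+")[[1]])
    } else NULL
    energy <- if (!is.null(fields$ENERGY_KCAL_MOL)) {
      as.numeric(fields$ENERGY_KCAL_MOL)
    } else NA_real_

    mol <- macro_molecule(name,
      data.frame(element = el, label = labels, ring_index = ring_index,
                 stringsAsFactors = FALSE),
      data.frame(i = bi, j = bj, order = orders, stringsAsFactors = FALSE),
      torsion_labels = torsion_labels, closure_bond = closure)
    mols[[length(mols) + 1L]] <- mol
    confs[[length(confs) + 1L]] <- conformer(xyz, energy = energy)
    # skip blank separator lines
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(mols)) parse_fail(path, 1L, "no SDF records found")
  list(molecule = mols[[1]], conformers = confs)
}
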