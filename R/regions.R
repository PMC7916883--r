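# Functional-region definitions: named residue sets with a monomer role
# ("own" = the monomer whose site is described, "other" = residues
# contributed across the dimer interface).

.expand_intervals <- function(x) {
  unlist(lapply(x, function(iv) seq(iv[1], iv[2])), use.names = FALSE)
}

#' Define a named residue region
#'
#' @param name Region name.
#' @param resno Integer vector of author residue numbers.
#' @param monomer `"own"` or `"other"`: which monomer of the dimer
#'   contributes the residues, relative to the monomer whose site is being
#'   described.
#' @return A tibble with columns `region`, `monomer`, `resno`.
#' @export
region_set <- function(name, resno, monomer = "own") {
  monomer <- match.arg(monomer, c("own", "other"))
  tibble(region = name, monomer = monomer, resno = as.integer(resno))
}

#' Built-in SHMT active-site and cofactor-site regions
#'
#' Residue sets describing the dimeric serine hydroxymethyltransferase
#' active-site cavity and cofactor sites, in the numbering of the
#' mesophilic (E. coli) crystal structure: the cavity "floor" (beta-strands
#' 197-202, 223-228, 237-242 plus their connecting loops, i.e. 197-204 and
#' 213-242), the inner "wall" (97-110 from the own monomer, 258-264 from
#' the other), the outer "wall" (174-182), the "roof" loop (118-133), the
#' pyridoxal-phosphate (PLP) site and the folate (H4PteGlu) site.
#'
#' @return A tibble with columns `region`, `monomer`, `resno`.
#' @export
#' @examples
#' dplyr::count(shmt_regions(), region)
shmt_regions <- function() {
  bind_rows(
    region_set("floor", .expand_intervals(list(c(197, 204), c(213, 242)))),
    region_set("inner_wall", 97:110, "own"),
    region_set("inner_wall", 258:264, "other"),
    region_set("outer_wall", 174:182, "own"),
    region_set("walls", 97:110, "own"),
    region_set("walls", 174:182, "own"),
    region_set("walls", 258:264, "other"),
    region_set("roof", 118:133, "own"),
    region_set("plp_site", c(35, 98, 99, 126, 175, 200, 203, 226, 228, 229, 235, 363), "own"),
    region_set("plp_site", c(55, 57, 65, 263), "other"),
    region_set("folate_site", c(121, 125, 127, 347), "own"),
    region_set("folate_site", c(57, 64), "other")
  )
}

#' Resolve a region set against a structure
#'
#' Assigns each region residue to a concrete chain of a dimer ("own"
#' residues to `own_chain`, "other" residues to `other_chain`) and checks
#' that every residue exists in the structure's C-alpha trace.
#'
#' @param regions A region tibble ([region_set()] / [shmt_regions()]).
#' @param x An `md_structure`.
#' @param own_chain,other_chain Chain identifiers of the monomer under
#'   analysis and of its partner.
#' @return A tibble with columns `region`, `chain`, `resno`.
#' @export
resolve_regions <- function(regions, x, own_chain = "A", other_chain = "B") {
  ca <- calpha_trace(x)
  out <- regions
  out$chain <- ifelse(out$monomer == "own", own_chain, other_chain)
  key <- paste(out$chain, out$resno)
  have <- paste(ca$chain, ca$resno)
  missing <- !(key %in% have)
  if (any(missing)) {
    bad <- out[missing, , drop = FALSE]
    abort(sprintf(
      "region residue(s) not present in structure: %s",
      paste(sprintf("%s:%d (%s)", bad$chain, bad$resno, bad$region)[
        seq_len(min(5, nrow(bad)))
      ], collapse = ", ")
    ))
  }
  out[, c("region", "chain", "resno")]
}

#' Read region definitions from a plain-text file
#'
#' One region per line: `name<whitespace>role<whitespace>residues`, where
#' role is `own` or `other` and residues is a comma-separated list of
#' numbers and `a-b` intervals. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A region tibble as from [region_set()].
#' @export
read_region_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\\s+")[[1]]
    if (length(parts) != 3) {
      abort(sprintf("malformed region definition on line %d: '%s'", i, lines[i]))
    }
    toks <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
    resno <- unlist(lapply(toks, function(t) {
      if (grepl("-", t, fixed = TRUE)) {
        ab <- as.integer(strsplit(t, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else {
        as.integer(t)
      }
    }))
    out[[i]] <- region_set(parts[1], resno, parts[2])
  }
  bind_rows(out)
}
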