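# element property lookup (masses in Da, van der Waals radii in Angstrom)

.loxdyn_env <- new.env(parent = emptyenv())

#' Element property table
#'
#' Masses (Da) and van der Waals radii (Angstrom, Bondi set) for the elements
#' encountered in protein/lipid systems, shipped as a plain-text table.
#' Elements absent from the table fall back to configurable defaults.
#'
#' @return data.frame with columns `element`, `mass`, `vdw_radius`.
#' @export
element_properties <- function() {
  if (is.null(.loxdyn_env$elements)) {
    path <- system.file("extdata", "element_properties.tsv", package = "loxdyn")
    .loxdyn_env$elements <- utils::read.table(path, header = TRUE, sep = "\t",
                                              stringsAsFactors = FALSE)
  }
  .loxdyn_env$elements
}

# vectorized lookup; unknown elements get the stated defaults
element_mass <- function(element, default = 12.0) {
  tab <- element_properties()
  m <- tab$mass[match(toupper(element), tab$element)]
  m[is.na(m)] <- default
  m
}

element_vdw <- function(element, default = 1.7) {
  tab <- element_properties()
  r <- tab$vdw_radius[match(toupper(element), tab$element)]
  r[is.na(r)] <- default
  r
}

# derive an element symbol from a PDB atom name when columns 77-78 are blank:
# strip digits/primes; unambiguous two-letter metal/halogen names are matched
# whole ("FE", "ZN", ...), everything else takes its leading character ("CA"
# in a protein record is C-alpha carbon, never calcium)
guess_element <- function(name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CU", "CL", "BR", "SE", "NA")
  vapply(name, function(nm) {
    s <- toupper(gsub("[0-9'\"]", "", trimws(nm)))
    if (!nzchar(s)) return("C")
    if (s %in% two_letter) return(s)
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}
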