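# ROI role assignment. Clinical structure names vary by centre, so roles are
# assigned from an ordered, case-insensitive regex table that users can
# replace with a plain-text config file ("role = regex" per line). The first
# matching role wins; unmatched names fall through to "other".

#' Default ROI-name patterns
#'
#' Ordered named character vector mapping role to a case-insensitive
#' (Perl-compatible) regex. Order matters: cornea and lens are tested before
#' eye so that names like "Lens_L" are not swallowed by a broad eye pattern,
#' and the brain pattern deliberately rejects "brainstem".
#'
#' @return Named character vector of regex patterns.
#' @export
default_role_patterns <- function() {
  c(cornea = "cornea",
    lens   = "lens",
    eye    = "eye|orbit|globe",
    ptv    = "ptv",
    brain  = "brain(?!stem)",
    body   = "body|external")
}

#' Assign a role to an ROI name
#'
#' @param name ROI name.
#' @param patterns Ordered named regex vector as from [default_role_patterns()].
#' @return A single role string ("other" when nothing matches).
#' @export
assign_role <- function(name, patterns = default_role_patterns()) {
  for (role in names(patterns)) {
    if (grepl(patterns[[role]], name, ignore.case = TRUE, perl = TRUE)) {
      return(role)
    }
  }
  "other"
}

#' Read a role-pattern config file
#'
#' Plain-text lines of the form `role = regex`; blank lines and lines starting
#' with `#` are ignored. Roles must be from the known set.
#'
#' @param path Path to the config file.
#' @return Named character vector usable as `patterns` in [assign_role()].
#' @export
read_role_patterns <- function(path) {
  if (!file.exists(path)) stop_io("role config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character(0)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_io("malformed role config line: ", ln)
    role <- trimws(kv[1])
    if (!role %in% c("eye", "lens", "cornea", "brain", "ptv", "body", "other")) {
      stop_io("unknown role in config: ", role)
    }
    out[[role]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}
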