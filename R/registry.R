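#' Acupoint registries
#'
#' An acupoint registry maps acupoint codes (e.g. \code{"PC6"}) to their
#' meridian and an optional display name. Codes are unique and compared
#' case-insensitively after trimming; extra-meridian "experience" points
#' carry the meridian \code{"NONE"}.
#'
#' @param code character vector of acupoint codes.
#' @param meridian character vector of meridian codes (one of
#'   \code{meridian_codes()}) or \code{"NONE"} for experience points.
#' @param display_name optional character vector of free-text names.
#' @return An object of class \code{acu_registry}: a data frame with columns
#'   \code{code}, \code{meridian}, \code{display_name}.
#' @seealso [csap_registry()] for the built-in registry of the chronic
#'   stable angina pectoris (CSAP) evidence base.
#' @export
acu_registry <- function(code, meridian, display_name = NA_character_) {
  code <- normalize_code(trimws(code))
  meridian <- toupper(trimws(meridian))
  if (anyDuplicated(toupper(code))) {
    stop("duplicate acupoint codes in registry: ",
         paste(unique(code[duplicated(toupper(code))]), collapse = ", "))
  }
  if (any(!nzchar(code))) stop("acupoint codes must be non-empty")
  bad <- setdiff(meridian, c(meridian_codes(), "NONE"))
  if (length(bad)) {
    stop("unknown meridian code(s): ", paste(unique(bad), collapse = ", "))
  }
  out <- data.frame(code = code, meridian = meridian,
                    display_name = rep_len(as.character(display_name), length(code)),
                    stringsAsFactors = FALSE)
  class(out) <- c("acu_registry", "data.frame")
  out
}

#' The ten meridian codes used in the CSAP evidence base
#'
#' @return Character vector of meridian abbreviations: pericardium (PC),
#'   lung (LU), heart (HT), stomach (ST), bladder (BL), ren/conception
#'   vessel (RN), large intestine (LI), liver (LR), spleen (SP), kidney (KI).
#' @export
meridian_codes <- function() {
  c("PC", "LU", "HT", "ST", "BL", "RN", "LI", "LR", "SP", "KI")
}

#' Built-in registry for the CSAP acupoint vocabulary
#'
#' The 37 acupoints observed across the 27 CSAP acupuncture prescriptions:
#' 36 traditional acupoints on 10 meridians plus the extra-meridian
#' experience point Xiongtong.
#'
#' @return An \code{acu_registry} with 37 rows.
#' @export
csap_registry <- function() {
  pts <- c(
    PC6 = "Neiguan", PC4 = "Ximen", PC2 = "Tianquan", PC3 = "Quze", PC7 = "Daling",
    LU9 = "Taiyuan", LU6 = "Kongzui", LU1 = "Zhongfu", LU7 = "Lieque",
    HT7 = "Shenmen", HT5 = "Tongli", HT1 = "Jiquan", HT3 = "Shaohai",
    HT4 = "Lingdao", HT6 = "Yinxi",
    ST36 = "Zusanli", ST40 = "Fenglong",
    BL15 = "Xinshu", BL14 = "Jueyinshu", BL17 = "Geshu", BL20 = "Pishu",
    BL23 = "Shenshu", BL13 = "Feishu",
    RN17 = "Danzhong", RN4 = "Guanyuan", RN6 = "Qihai", RN14 = "Juque",
    RN12 = "Zhongwan",
    LI11 = "Quchi", LI4 = "Hegu",
    LR3 = "Taichong",
    SP6 = "Sanyinjiao", SP10 = "Xuehai", SP8 = "Diji", SP9 = "Yinlingquan",
    KI3 = "Taixi"
  )
  codes <- c(names(pts), "Xiongtong")
  mer <- c(sub("[0-9]+$", "", names(pts)), "NONE")
  acu_registry(codes, mer, c(unname(pts), "Xiongtong (experience point)"))
}

#' Read a registry from a delimited text file
#'
#' Expects columns \code{code}, \code{meridian} and optionally
#' \code{display_name}.
#'
#' @param path file path.
#' @param sep field separator, default comma.
#' @return An \code{acu_registry}.
#' @export
read_registry <- function(path, sep = ",") {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("code", "meridian")
  if (!all(need %in% names(df))) {
    stop("registry file must have columns 'code' and 'meridian'")
  }
  acu_registry(df$code, df$meridian,
               if ("display_name" %in% names(df)) df$display_name else NA_character_)
}

#' Write a registry to a delimited text file
#'
#' @param registry an \code{acu_registry}.
#' @param path output file path.
#' @param sep field separator, default comma.
#' @return Invisibly, \code{path}.
#' @export
write_registry <- function(registry, path, sep = ",") {
  stopifnot(inherits(registry, "acu_registry"))
  utils::write.table(registry, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the meridian of an acupoint code
#'
#' @param code acupoint code (case-insensitive, trimmed).
#' @param registry an \code{acu_registry}; defaults to [csap_registry()].
#' @return The meridian code, or \code{"NONE"} for extra-meridian points.
#' @export
#' @examples
#' meridian_of("PC6")   # "PC"
#' meridian_of("Xiongtong")  # "NONE"
meridian_of <- function(code, registry = csap_registry()) {
  i <- match(toupper(trimws(code)), toupper(registry$code))
  if (anyNA(i)) {
    stop("acupoint code(s) not in registry: ",
         paste(code[is.na(i)], collapse = ", "))
  }
  registry$meridian[i]
}

# Canonical code form: meridian-style codes (letters + number) are upper-cased;
# anything else (experience-point names such as "Xiongtong") is kept verbatim
# after trimming. With a registry, the registry's spelling wins.
normalize_code <- function(code, registry = NULL) {
  code <- trimws(code)
  if (!is.null(registry)) {
    i <- match(toupper(code), toupper(registry$code))
    hit <- !is.na(i)
    code[hit] <- registry$code[i[hit]]
    code[!hit] <- normalize_code(code[!hit])
    return(code)
  }
  std <- grepl("^[A-Za-z]{1,3}[0-9]+$", code)
  code[std] <- toupper(code[std])
  code
}

#' @export
print.acu_registry <- function(x, ...) {
  cat("Acupoint registry:", nrow(x), "codes (",
      sum(x$meridian != "NONE"), "meridian,",
      sum(x$meridian == "NONE"), "extra-meridian )\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
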