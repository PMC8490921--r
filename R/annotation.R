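#' @keywords internal
"_PACKAGE"

# Receptor subdomains carrying Ballesteros-Weinstein style numbering.
# Transmembrane helices use their helix index as prefix; intracellular /
# extracellular loops use the two-digit prefix of their flanking helices
# (ICL2 sits between TM3 and TM4, hence 34.X); helix 8 uses prefix 8.
bw_prefixes <- c(
  TM1 = "1", TM2 = "2", TM3 = "3", TM4 = "4", TM5 = "5", TM6 = "6",
  TM7 = "7", H8 = "8",
  ICL1 = "12", ECL1 = "23", ICL2 = "34", ECL2 = "45", ICL3 = "56",
  ECL3 = "67"
)

# Partner subdomain vocabulary (G-alpha elements and arrestin loops);
# unknown names are accepted as positional subdomains with a warning.
partner_subdomains <- c(
  "HN", "hns1", paste0("S", 1:6), "h4s6", "H5",
  "finger_loop", "middle_loop", "C_loop", "lariat_loop", "bottom_loop"
)

#' Load a subdomain annotation table
#'
#' Reads a tab-separated file with header
#' \code{chain  subdomain  start  end  anchor} describing subdomain spans in
#' author numbering. The anchor column gives the author residue number of the
#' X.50 reference residue and may be blank: receptor subdomains without an
#' anchor fall back to author numbering (the usual treatment of poorly
#' conserved stretches such as ICL3), partner subdomains are always numbered
#' positionally from the span start.
#'
#' @param path Path to the annotation TSV.
#' @return An \code{AnnotationTable}: a data frame with columns \code{chain},
#'   \code{subdomain}, \code{start}, \code{end}, \code{anchor} (NA when
#'   blank) and \code{scheme}.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "integer", "character"))
  need <- c("chain", "subdomain", "start", "end", "anchor")
  if (!all(need %in% names(tab))) {
    stop("annotation header must be: ", paste(need, collapse = "  "))
  }
  tab$anchor <- suppressWarnings(as.integer(tab$anchor))
  annotation_table(tab)
}

#' Build an annotation table from a data frame
#'
#' @param tab Data frame with columns \code{chain}, \code{subdomain},
#'   \code{start}, \code{end}, \code{anchor}.
#' @return Validated \code{AnnotationTable}.
#' @export
annotation_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (!"anchor" %in% names(tab)) tab$anchor <- NA_integer_
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$anchor <- as.integer(tab$anchor)
  if (any(tab$start > tab$end)) {
    stop("annotation span with start > end")
  }
  ok_anchor <- is.na(tab$anchor) |
    (tab$anchor >= tab$start & tab$anchor <= tab$end)
  if (!all(ok_anchor)) {
    stop("anchor outside its span for subdomain ",
         tab$subdomain[!ok_anchor][1L])
  }
  for (ch in unique(tab$chain)) {
    sp <- tab[tab$chain == ch, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) > 1L && any(sp$start[-1L] <= sp$end[-nrow(sp)])) {
      stop("overlapping subdomain spans on chain ", ch)
    }
  }
  known_bw <- tab$subdomain %in% names(bw_prefixes)
  known_partner <- tab$subdomain %in% partner_subdomains
  unknown <- !known_bw & !known_partner
  if (any(unknown)) {
    warning("unknown subdomain name(s) treated as positional: ",
            paste(unique(tab$subdomain[unknown]), collapse = ", "))
  }
  tab$scheme <- ifelse(known_bw & !is.na(tab$anchor),
                       ifelse(nchar(bw_prefixes[tab$subdomain]) == 2L,
                              "loop_bw", "bw"),
                       ifelse(known_bw, "author", "partner_positional"))
  rownames(tab) <- NULL
  class(tab) <- c("AnnotationTable", "data.frame")
  tab
}

#' Assign generic residue labels from an annotation table
#'
#' For Ballesteros-Weinstein subdomains the anchor residue receives label
#' \code{<prefix>.50} and a residue at offset k from the anchor receives
#' \code{<prefix>.(50+k)}; intracellular loop 2 uses prefix 34 (between TM3
#' and TM4), the other receptor loops 12/23/45/56/67 analogously and helix 8
#' the prefix 8. Partner subdomains are numbered sequentially from the span
#' start (\code{H5.01}, \code{H5.02}, ...). Residues covered by no span (and
#' spans without an anchor on receptor subdomains) keep author numbering with
#' label \code{<chain>:<resnum>}.
#'
#' @param model A \code{StructureModel}.
#' @param table An \code{AnnotationTable}.
#' @return A \code{LabelMap}: data frame with one row per residue of the
#'   model, columns \code{chain}, \code{resnum}, \code{icode},
#'   \code{resname}, \code{subdomain}, \code{label}, \code{scheme}.
#' @examples
#' toy <- make_toy_complex(n = 12, separation = 6)
#' map <- assign_labels(toy$model, toy$annotation)
#' head(map)
#' @export
assign_labels <- function(model, table) {
  stopifnot(inherits(table, "AnnotationTable"))
  res <- residue_table(model)
  res$subdomain <- NA_character_
  res$label <- paste0(res$chain, ":", res$resnum, res$icode)
  res$scheme <- "author"
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    hit <- res$chain == row$chain & res$resnum >= row$start &
      res$resnum <= row$end
    span_res <- res$resnum[hit]
    missing <- setdiff(seq(row$start, row$end), span_res)
    if (length(missing) > 0L) {
      message("annotation span ", row$subdomain, " (chain ", row$chain,
              "): ", length(missing), " residue(s) absent from model")
    }
    if (!any(hit)) next
    res$subdomain[hit] <- row$subdomain
    if (row$scheme %in% c("bw", "loop_bw")) {
      prefix <- bw_prefixes[[row$subdomain]]
      pos <- 50L + res$resnum[hit] - row$anchor
      if (any(pos <= 0L)) {
        stop("annotation span ", row$subdomain,
             " too wide: position index below 1 (shift start or anchor)")
      }
      res$label[hit] <- paste0(prefix, ".", pos)
      res$scheme[hit] <- row$scheme
    } else if (row$scheme == "partner_positional") {
      pos <- res$resnum[hit] - row$start + 1L
      res$label[hit] <- paste0(row$subdomain, ".", sprintf("%02d", pos))
      res$scheme[hit] <- "partner_positional"
    }
    # receptor subdomain without anchor: keep author labels (ICL3-style)
  }
  if (anyDuplicated(res$label)) {
    stop("duplicate generic labels produced; check annotation spans")
  }
  rownames(res) <- NULL
  class(res) <- c("LabelMap", "data.frame")
  res
}

#' Resolve a generic label back to its residue
#'
#' @param mapping A \code{LabelMap} from \code{\link{assign_labels}}.
#' @param label A label string, e.g. \code{"3.50"} or \code{"H5.23"}.
#' @return One-row data frame identifying the residue, or \code{NULL} when
#'   the label is absent.
#' @export
label_lookup <- function(mapping, label) {
  stopifnot(inherits(mapping, "LabelMap"))
  hit <- which(mapping$label == label)
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L) stop("label '", label, "' is not unique in mapping")
  mapping[hit, , drop = FALSE]
}
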