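#' RIP-qPCR crossing-point (Cp) table
#'
#' Long-format record of a RIP-qPCR experiment: one row per
#' `(gene, role, rt, bio_rep, tech_rep)` with its Cp value. Roles are
#' `input` (diluted input extract), `ip` (specific immunoprecipitate) and
#' `mock` (non-specific control IP); `rt` is `plus` or `minus` (no reverse
#' transcriptase, the genomic/plasmid contamination control). A missing Cp
#' (`NA`) means not detected within the run (45 cycles); it is a distinct
#' state, never a sentinel number.
#'
#' @param df data frame with columns `gene, role, rt, bio_rep, tech_rep, cp`.
#' @return The validated data frame with class `cp_table`.
#' @export
as_cp_table <- function(df) {
  need <- c("gene", "role", "rt", "bio_rep", "tech_rep", "cp")
  if (!all(need %in% names(df)))
    stop("cp table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% c("input", "ip", "mock")))
    stop("role must be one of: input, ip, mock")
  if (!all(df$rt %in% c("plus", "minus")))
    stop("rt must be 'plus' or 'minus'")
  if (anyDuplicated(df[, c("gene", "role", "rt", "bio_rep", "tech_rep")]))
    stop("duplicate (gene, role, rt, bio_rep, tech_rep) combinations")
  if (any(df$cp < 0, na.rm = TRUE)) stop("Cp values must be >= 0")
  class(df) <- c("cp_table", "data.frame")
  df
}

#' @rdname as_cp_table
#' @param path CSV path with the same columns (`cp` empty = not detected).
#' @export
read_cp_table <- function(path) {
  as_cp_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname as_cp_table
#' @param x a `cp_table`.
#' @export
write_cp_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Percent input RNA recovered in an immunoprecipitate
#'
#' `100 * 2^((cp_input - input_correction) - cp_ip)`. The default correction
#' of 6.644 Cp (= log2 of 100, to the printed precision) accounts for the
#' fraction of extract saved as input and its dilution before cDNA synthesis
#' (10% input, diluted 1:10); labs using other input fractions should set
#' `input_correction = log2(1 / input_fraction)`. Vectorised; `NA` Cp values
#' propagate to `NA`.
#'
#' One-cycle shifts act multiplicatively: lowering `cp_ip` by one cycle
#' doubles the value, lowering `cp_input` by one halves it.
#'
#' @param cp_input Cp of the (diluted) input sample.
#' @param cp_ip Cp of the IP sample.
#' @param input_correction dilution-correction constant in Cp units.
#' @return Percent of input recovered (numeric, same length as input).
#' @export
percent_input <- function(cp_input, cp_ip, input_correction = 6.644) {
  100 * 2^((cp_input - input_correction) - cp_ip)
}

#' Fold enrichment of an IP over the mock IP (delta-delta-Cp)
#'
#' With input Cp values supplied, the input-normalised double delta
#' `2^((cp_mock - cp_input_mock) - (cp_ip - cp_input_ip))`; without them, the
#' single-delta fallback `2^(cp_mock - cp_ip)` (flagged via the
#' `"single_delta"` attribute). Supplying only one of the two input Cp values
#' is an error.
#'
#' @param cp_ip,cp_mock Cp of the specific and mock IPs.
#' @param cp_input_ip,cp_input_mock optional input Cp measured alongside each
#'   IP (both or neither).
#' @return Fold enrichment (attribute `single_delta` records the variant).
#' @export
fold_enrichment <- function(cp_ip, cp_mock,
                            cp_input_ip = NULL, cp_input_mock = NULL) {
  if (is.null(cp_input_ip) != is.null(cp_input_mock))
    stop("supply both input Cp values or neither")
  if (is.null(cp_input_ip)) {
    structure(2^(cp_mock - cp_ip), single_delta = TRUE)
  } else {
    structure(2^((cp_mock - cp_input_mock) - (cp_ip - cp_input_ip)),
              single_delta = FALSE)
  }
}

#' Fold enrichment of a target gene relative to a reference gene
#'
#' Ratio of two [fold_enrichment()] values (e.g. a target mRNA relative to
#' the partner mRNA it is compared against).
#'
#' @param fe_target,fe_reference fold enrichments; `fe_reference > 0`.
#' @return `fe_target / fe_reference`.
#' @export
relative_fold_enrichment <- function(fe_target, fe_reference) {
  if (any(fe_reference <= 0, na.rm = TRUE))
    stop("reference fold enrichment must be > 0")
  as.numeric(fe_target) / as.numeric(fe_reference)
}

#' Reference-normalised expression change between two conditions
#'
#' The classic delta-delta-Cp expression statistic: target Cp normalised to a
#' reference gene (e.g. Gapdh) in each condition, then compared across
#' conditions: `2^-((cp_target_c1 - cp_ref_c1) - (cp_target_c2 - cp_ref_c2))`.
#'
#' @param cp_target_c1,cp_ref_c1 target and reference Cp in condition 1.
#' @param cp_target_c2,cp_ref_c2 target and reference Cp in condition 2.
#' @return Fold change of condition 1 relative to condition 2.
#' @export
relative_expression <- function(cp_target_c1, cp_ref_c1,
                                cp_target_c2, cp_ref_c2) {
  2^-((cp_target_c1 - cp_ref_c1) - (cp_target_c2 - cp_ref_c2))
}

#' Minus-RT contamination quality control
#'
#' For each `(gene, role)`, compares the technical-replicate-averaged +RT and
#' -RT Cp values: the control passes when the -RT Cp exceeds the +RT Cp by at
#' least `min_gap` cycles (default 10). A -RT reaction that never crossed
#' threshold within the run counts as a pass. Combinations failing QC should
#' be excluded from downstream statistics; [aggregate_replicates()] does so
#' by default.
#'
#' @param table a [as_cp_table()] table.
#' @param min_gap minimum Cp gap (cycles) between -RT and +RT.
#' @return Data frame `gene, role, cp_plus, cp_minus, gap, pass`; a warning
#'   is raised (and an empty report returned) when no -RT rows exist.
#' @export
rt_minus_qc <- function(table, min_gap = 10) {
  table <- as_cp_table(as.data.frame(table))
  if (!any(table$rt == "minus")) {
    warning("no -RT rows: contamination QC skipped")
    return(data.frame(gene = character(), role = character(),
                      cp_plus = numeric(), cp_minus = numeric(),
                      gap = numeric(), pass = logical()))
  }
  agg <- stats::aggregate(cp ~ gene + role + rt, data = table, FUN = mean,
                          na.action = stats::na.pass)
  plus <- agg[agg$rt == "plus", ]
  minus <- agg[agg$rt == "minus", ]
  rep <- merge(plus[, c("gene", "role", "cp")],
               minus[, c("gene", "role", "cp")],
               by = c("gene", "role"), all.x = TRUE,
               suffixes = c("_plus", "_minus"))
  names(rep)[names(rep) == "cp_plus"] <- "cp_plus"
  rep$gap <- rep$cp_minus - rep$cp_plus
  rep$pass <- is.na(rep$cp_minus) | rep$gap >= min_gap
  rep[order(rep$gene, rep$role), ]
}

#' Aggregate a Cp table into enrichment statistics
#'
#' Replicate handling follows the qPCR convention: technical replicates are
#' averaged on the Cp (log) scale first, then the statistic is computed per
#' biological replicate, then summarised as mean and SD across biological
#' replicates (per-replicate values are retained — the figures plot the
#' individual dots). `(gene, role)` combinations failing the -RT QC are
#' excluded by default. The result is invariant to row order of the input.
#'
#' @param table a [as_cp_table()] table (or plain data frame).
#' @param statistic `"percent_input"`, `"fold_enrichment"` or
#'   `"relative_fold_enrichment"`.
#' @param genes genes to report (default: all in the table).
#' @param reference_gene reference for `relative_fold_enrichment`.
#' @param input_correction passed to [percent_input()].
#' @param use_input for `fold_enrichment`: normalise by input Cp when
#'   available (double delta) rather than the single-delta fallback.
#' @param apply_qc drop (gene, role) combinations failing [rt_minus_qc()].
#' @return List with `summary` (data frame `gene, statistic, value, sd,
#'   n_bio, flag`) and `replicates` (per-biological-replicate values).
#' @export
aggregate_replicates <- function(table,
                                 statistic = c("percent_input",
                                               "fold_enrichment",
                                               "relative_fold_enrichment"),
                                 genes = NULL, reference_gene = NULL,
                                 input_correction = 6.644,
                                 use_input = TRUE, apply_qc = TRUE) {
  statistic <- match.arg(statistic)
  table <- as_cp_table(as.data.frame(table))
  if (apply_qc && any(table$rt == "minus")) {
    qc <- rt_minus_qc(table)
    bad <- qc[!qc$pass, c("gene", "role")]
    if (nrow(bad))
      table <- table[!paste(table$gene, table$role) %in%
                       paste(bad$gene, bad$role), , drop = FALSE]
  }
  plus <- table[table$rt == "plus" & !is.na(table$cp), , drop = FALSE]
  if (!nrow(plus)) stop("no detected +RT rows to aggregate")
  # technical replicates averaged on the Cp scale
  tech <- stats::aggregate(cp ~ gene + role + bio_rep, data = plus,
                           FUN = mean)
  tech <- tech[order(tech$gene, tech$role, tech$bio_rep), ]
  if (is.null(genes)) genes <- sort(unique(tech$gene))

  per_bio <- function(g) {
    sub <- tech[tech$gene == g, ]
    wide <- stats::reshape(sub, idvar = "bio_rep", timevar = "role",
                           direction = "wide")
    names(wide) <- sub("^cp\\.", "", names(wide))
    wide
  }
  rep_rows <- list(); sum_rows <- list()
  for (g in genes) {
    wide <- per_bio(g)
    flag <- ""
    vals <- switch(statistic,
      percent_input = {
        if (!all(c("input", "ip") %in% names(wide))) NULL
        else percent_input(wide$input, wide$ip, input_correction)
      },
      fold_enrichment = {
        if (!all(c("ip", "mock") %in% names(wide))) NULL
        else if (use_input && "input" %in% names(wide)) {
          fold_enrichment(wide$ip, wide$mock, wide$input, wide$input)
        } else {
          flag <- "single_delta"
          fold_enrichment(wide$ip, wide$mock)
        }
      },
      relative_fold_enrichment = {
        if (is.null(reference_gene))
          stop("relative_fold_enrichment needs a reference_gene")
        wr <- per_bio(reference_gene)
        if (!all(c("ip", "mock") %in% names(wide)) ||
            !all(c("ip", "mock") %in% names(wr)) ||
            nrow(wide) != nrow(wr)) NULL
        else {
          flag <- if (use_input && "input" %in% names(wide) &&
                      "input" %in% names(wr)) "" else "single_delta"
          ft <- if (flag == "") fold_enrichment(wide$ip, wide$mock,
                                                wide$input, wide$input)
                else fold_enrichment(wide$ip, wide$mock)
          fr <- if (flag == "") fold_enrichment(wr$ip, wr$mock,
                                                wr$input, wr$input)
                else fold_enrichment(wr$ip, wr$mock)
          relative_fold_enrichment(ft, fr)
        }
      })
    if (is.null(vals)) {
      sum_rows[[g]] <- data.frame(gene = g, statistic = statistic,
                                  value = NA_real_, sd = NA_real_,
                                  n_bio = 0L, flag = "missing role")
      next
    }
    vals <- as.numeric(vals)
    rep_rows[[g]] <- data.frame(gene = g, bio_rep = wide$bio_rep,
                                value = vals)
    sum_rows[[g]] <- data.frame(
      gene = g, statistic = statistic, value = mean(vals, na.rm = TRUE),
      sd = if (sum(!is.na(vals)) > 1) stats::sd(vals, na.rm = TRUE)
           else NA_real_,
      n_bio = sum(!is.na(vals)), flag = flag)
  }
  list(summary = do.call(rbind, c(sum_rows, list(make.row.names = FALSE))),
       replicates = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))))
}

#' Bar-with-dots plot of aggregated enrichment statistics
#'
#' Bars are the mean across biological replicates, whiskers +-1 SD, dots the
#' individual replicate values.
#'
#' @param agg result of [aggregate_replicates()].
#' @param ylab y-axis label (defaults to the statistic name).
#' @return Invisibly, `agg`.
#' @export
plot_enrichment_records <- function(agg, ylab = NULL) {
  s <- agg$summary[!is.na(agg$summary$value), , drop = FALSE]
  if (!nrow(s)) stop("nothing to plot")
  if (is.null(ylab)) ylab <- gsub("_", " ", s$statistic[1])
  ymax <- max(c(s$value + ifelse(is.na(s$sd), 0, s$sd),
                agg$replicates$value), na.rm = TRUE)
  bp <- graphics::barplot(s$value, names.arg = s$gene, ylab = ylab,
                          ylim = c(0, 1.1 * ymax), col = "grey85")
  ok <- !is.na(s$sd)
  graphics::arrows(bp[ok], s$value[ok] - s$sd[ok], bp[ok],
                   s$value[ok] + s$sd[ok],
                   angle = 90, code = 3, length = 0.05)
  for (i in seq_len(nrow(s))) {
    r <- agg$replicates[agg$replicates$gene == s$gene[i], "value"]
    graphics::points(rep(bp[i], length(r)) + stats::runif(length(r), -.1, .1),
                     r, pch = 16, cex = 0.7)
  }
  invisible(agg)
}
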