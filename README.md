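# mipclass

Subfamily classification of major intrinsic proteins (MIPs — the
aquaporin/aquaglyceroporin channel family), with a focus on the LIP
("large intrinsic protein") group of heterokont algae.

MIP subfamilies are recognisable from three kinds of evidence, and the
package implements all three from first principles:

* **NPA-box motifs** — the two Asn-Pro-Ala tripeptides on loops B and E
  of the MIP fold, whose variants (NPM, NPG, NGA) mark subfamilies. A
  deterministic scanner locates the box pair and labels it.
* **The ar/R selectivity filter** — one residue each from helices 2 and
  5 plus two from the loop-E region (roles H2, H5, LE1, LE2), read off a
  global pairwise alignment to an annotated reference (packaged synthetic
  stand-ins carrying the published HsAQP1 and EcGlpF annotations).
  Rule-based lookup turns complete filters into substrate calls:
  glycerol permease (W/V/[A,G]/R) or water channel (F/H/[A,C]/R).
* **Phylogenetic placement** — maximum-likelihood pairwise distances
  under the JTT substitution model, a from-scratch Saitou–Nei
  neighbour-joining implementation (Studier–Keppler criterion,
  deterministic tie-breaks), and column-resampling bootstrap supports.

The LIP subfamily is delineated by its filter signature — proline at
LE1 with leucine/isoleucine at LE2 — typically corroborated by an NPM
second box, W/Y at H2 and a C-terminal lysine.

Because real proteomes are out of scope, the package ships a simulator
that plants all of these features with exact recorded truth (including
true alignments), plus a fixed 20-protein heterokont panel encoding the
published feature table. The methods vignette
(`vignettes/mip-classification-methods.Rmd`) documents the model,
generator design, numerical choices and limitations.

## Worked example

```r
library(mipclass)

panel <- generate_heterokont_panel(seed = 42)
scan  <- scan_npa_boxes(panel$sequences)
head(scan[, c("seq_id", "box1", "pos1", "box2", "pos2", "label")], 5)
#>   seq_id box1 pos1 box2 pos2      label
#> 1 TpMIP1  NPA   78  NPA  185  canonical
#> 2 TpMIP2  NPA   78  NPM  185 second_NPM
#> 3 ToMIP1  NPA   78  NPM  185 second_NPM
#> 4 ToMIP2  NPA   78  NPA  185  canonical
#> 5 PtMIP1  NPA   78  NPA  185  canonical

extract_arr_filter(panel$sequences["EsMIP"])[, c("seq_id", "ref_used", "filter")]
#>   seq_id ref_used filter
#> 1  EsMIP   HsAQP1   WLPI

calls <- classify_sequences(panel$sequences)
summarize_calls(calls)$by_subfamily
#>          GIP          LIP unclassified
#>            3            9            8

calls$evidence[calls$seq_id == "EsMIP"]
#> "filter:WLPI; boxes:NPA/NPM; specificity:unknown(rule none);
#>  lip_signature:LE1=P,LE2 in {L,I} (NPM=TRUE, ctermK=TRUE, H2 W/Y=TRUE)"
```

The nine LIP calls are EsMIP, NgMIP, PtMIP5, PnmMIP, FcMIP, AaMIP1,
SarMIP, TpMIP2 and ToMIP1; the three glycerol permeases are
PtMIP1–PtMIP3, and EsAQP, EsPIP, AaMIP4 and PtMIP4 score as water
channels — for any panel seed.

The full pipeline (simulate/load → validate → scan → filter extraction
→ alignment → tree with bootstrap → classify → summary) runs from one
config and writes every stage output plus a manifest:

```r
run_pipeline(list(
  input = list(simulate = list(what = "panel", seed = 42)),
  msa = "true-alignment", bootstrap_reps = 100, bootstrap_seed = 7,
  outdir = "run1"))
```

Reruns with the same config are byte-identical.

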