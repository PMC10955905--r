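# fenplan

Automated geometric planning of **fenestrated endovascular aneurysm repair
(FEVAR)** on commercially available stent grafts.

## The problem

Juxtarenal and suprarenal aortic aneurysms leave too little healthy aorta
below the visceral vessels for a standard endograft to seal.  Surgeons
therefore hand-modify commercial tube grafts before implantation, cutting
**fenestrations** — holes that preserve flow into the celiac artery (CA),
superior mesenteric artery (SMA) and the renal arteries (RRA/LRA) — with a
cautery tool.  Each fenestration must land on its target ostium *and* miss
the metal strut rings, which cannot be cauterized.  Finding a graft
rotation/translation that satisfies both constraints for four vessels at
once is tedious and error-prone when done by hand.

`fenplan` automates the search.  Both the graft and the patient's visceral
anatomy are flattened into a common 2D coordinate system:

* **AL** (arclength): circumferential position around the graft,
  `AL = phi/360 * pi * D` at the deployed diameter `D`;
* **PGD** (proximal graft distance): axial distance from the top of the
  graft.

The graft template is rasterized into a binary **strut mask** (periodic in
AL); the measured ostia become a rigid constellation of discs in a
**fenestration mask**.  Sliding one mask over the other (2D
cross-correlation, circular in AL) enumerates every alignment with zero
strut overlap; among those the planner picks the one minimizing the summed
surface deviation per vessel,

```
delta = sqrt(dAL^2 + dPGD^2)   [mm, AL on the shorter arc]
```

If no rigid alignment exists, the renal fenestrations may shift
independently up to **3 mm posteriorly** in AL (prioritized vessels — CA,
SMA — never move).  The chosen design is then mapped onto a 3D graft mesh
lofted along the aortic centerline: the cut mesh is flattened onto a
rectangle with a **cotangent-weight Laplacian harmonic embedding**
(`L = D − W`, `w_ij = (cot α_ij + cot β_ij)/2`, solved as
`L_II v_I = −L_IB v_B`), and points travel between the 2D design and the 3D
surface through **barycentric coordinates** (`λ = T⁻¹(r − r₃)`,
`λ₁+λ₂+λ₃ = 1`).  Outputs are operating-room modification instructions
(CSV + diagram) and a textured OBJ of the final design.

## Worked example

```r
library(fenplan)

case <- generate_case("tortuous", noise_sd = 0.25, seed = 21)  # synthetic CT
report <- plan_fenestrations(list(
  labelmap = case$labelmap, spacing = case$spacing,
  ostia = case$ostia_truth[, c("vessel","x","y","z","diameter","prioritized")],
  template = "thoracic-straight-30",
  graft_top_station = case$graft_top_station,
  out_dir = "plan-out"))
report
```

```
<plan_report> template thoracic-straight-30, deployed D = 25.9 mm: VALID plan
  vessel AL_mm PGD_mm diameter_mm relaxation_mm
1     CA  6.25  20.71         7.0             0
2    SMA 80.68  37.70         7.0             0
3    RRA 23.53  39.03         5.5             0
4    LRA 57.65  42.51         5.5             0
```

Each row is one cautery instruction: cut a hole of `diameter_mm` centred
`AL_mm` millimetres around the fabric (clockwise from the anterior datum,
viewed from the proximal end) and `PGD_mm` millimetres down from the top of
the graft.  `relaxation_mm` is nonzero only when a renal fenestration had
to yield posteriorly to clear a strut.  `plan-out/` receives the CSV, a
labelled diagram (`instructions.png`), a JSON report and a textured
`graft_design.obj`.

A thin command-line interface wraps the same functions:

```sh
fenplan simulate --profile tortuous --seed 21 --out case/
fenplan plan --config plan.json --out plan-out/     # exit 0 valid, 2 no fit
fenplan flatten --template thoracic-straight-30 --out mask.png
```

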