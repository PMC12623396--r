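<?xml version="1.0" encoding="UTF-8"?>
<!-- Transfemoral (TF) running-specific prosthesis model definition.
     Placeholders: {s} prosthetic-side prefix (L/R), {c} contralateral
     (sound) side prefix, {p}/{q} the same in lowercase for joint names.
     Sound-side segment recipes are ISB-default (pelvis from ASIS/PSIS,
     thigh HJC-epicondyles, shank epicondyles-malleoli, foot
     heel-metatarsals). -->
<model name="rsp-tf" level="TF" rpf_shapes="C">
  <markers>
    <!-- socket technical cluster; MAD is removed after the static trial -->
    <marker name="{s}FAP" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}FAD" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}LAP" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}LAD" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}MAD" type="technical" class="static" segment="socket" host="socket"/>
    <marker name="{s}GT" type="anatomical" class="permanent" segment="socket"/>
    <!-- socket-clamp screws, wand-calibrated against the socket cluster -->
    <marker name="{s}WAM" type="mechanical" class="wand" segment="socket_clamp" host="socket"/>
    <marker name="{s}WAL" type="mechanical" class="wand" segment="socket_clamp" host="socket"/>
    <marker name="{s}WPM" type="mechanical" class="wand" segment="socket_clamp" host="socket"/>
    <marker name="{s}WPL" type="mechanical" class="wand" segment="socket_clamp" host="socket"/>
    <!-- knee hinge axis: measured directly, never SVD-reconstructed -->
    <marker name="{s}KL" type="mechanical" class="permanent" segment="knee"/>
    <marker name="{s}KM" type="mechanical" class="permanent" segment="knee"/>
    <!-- foot-clamp plaque screws (4-hole adapter), wand-calibrated against
         the technical proximal-RPF cluster -->
    <marker name="{s}CLAL" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <marker name="{s}CLPL" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <marker name="{s}CLAM" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <marker name="{s}CLPM" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <!-- technical proximal-RPF T-frame cluster -->
    <marker name="{s}FPA" type="technical" class="static" segment="rpf_proximal" host="rpf_proximal"/>
    <marker name="{s}FP1" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FP2" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FP3" type="technical" class="permanent" segment="rpf_proximal"/>
    <!-- distal RPF tip -->
    <marker name="{s}FDA" type="technical" class="permanent" segment="rpf_distal"/>
    <marker name="{s}FDM" type="technical" class="permanent" segment="rpf_distal"/>
    <marker name="{s}FDL" type="technical" class="permanent" segment="rpf_distal"/>
    <!-- pelvis and sound side (ISB-default) -->
    <marker name="RASI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="LASI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="RPSI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="LPSI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="{s}HJC" type="anatomical" class="virtual" segment="pelvis" host="pelvis"/>
    <marker name="{c}HJC" type="anatomical" class="virtual" segment="pelvis" host="pelvis"/>
    <marker name="{c}LEP" type="anatomical" class="permanent" segment="thigh"/>
    <marker name="{c}MEP" type="anatomical" class="permanent" segment="thigh"/>
    <marker name="{c}LML" type="anatomical" class="permanent" segment="shank"/>
    <marker name="{c}MML" type="anatomical" class="permanent" segment="shank"/>
    <marker name="{c}CAL" type="anatomical" class="permanent" segment="foot"/>
    <marker name="{c}MT1" type="anatomical" class="permanent" segment="foot"/>
    <marker name="{c}MT5" type="anatomical" class="permanent" segment="foot"/>
  </markers>
  <clusters>
    <cluster segment="socket" markers="{s}FAP,{s}FAD,{s}LAP,{s}LAD,{s}MAD"/>
    <cluster segment="rpf_proximal" markers="{s}FP1,{s}FP2,{s}FP3,{s}FPA"/>
    <cluster segment="pelvis" markers="RASI,LASI,RPSI,LPSI"/>
  </clusters>
  <frames>
    <frame tag="PL" recipe="pelvis" inputs="RASI,LASI,RPSI,LPSI" side="none"/>
    <frame tag="{s}SK" recipe="socket" inputs="{s}LAP,{s}LAD,{s}MAD,{s}FAP,{s}FAD" side="prosthetic"/>
    <frame tag="{s}SC" recipe="socket_clamp" inputs="{s}WAL,{s}WAM,{s}WPL,{s}WPM" side="prosthetic"/>
    <frame tag="{s}FC" recipe="foot_clamp_C" inputs="{s}CLAL,{s}CLPL,{s}CLAM,{s}CLPM" side="prosthetic"/>
    <frame tag="{s}PK" recipe="knee_pk" inputs="{s}KL,{s}KM" depends="{s}SC" side="prosthetic"/>
    <frame tag="{s}DK" recipe="knee_dk" inputs="{s}KL,{s}KM" depends="{s}FC" side="prosthetic"/>
    <frame tag="{s}FD" recipe="distal_rpf" inputs="{s}FDA,{s}FDM,{s}FDL" side="prosthetic"/>
    <frame tag="{s}FP" recipe="technical_fp" inputs="{s}FP1,{s}FP2,{s}FP3" side="prosthetic"/>
    <frame tag="{s}HJCK" recipe="hjc_k" inputs="{s}HJC,{s}KL,{s}KM" side="prosthetic"/>
    <frame tag="{s}GTKL" recipe="gt_kl" inputs="{s}GT,{s}KL" side="prosthetic"/>
    <frame tag="{c}TH" recipe="thigh" inputs="{c}HJC,{c}LEP,{c}MEP" side="sound"/>
    <frame tag="{c}SH" recipe="shank" inputs="{c}LEP,{c}MEP,{c}LML,{c}MML" side="sound"/>
    <frame tag="{c}FT" recipe="foot" inputs="{c}CAL,{c}MT1,{c}MT5" side="sound"/>
  </frames>
  <chain>
    <joint name="{p}htf" prox="PL" dist="{s}SK" sequence="zxy" flip="1,1,1"/>
    <joint name="{p}ktf" prox="{s}PK" dist="{s}DK" sequence="zxy" flip="-1,1,1"/>
    <joint name="{p}atf" prox="{s}FC" dist="{s}FD" sequence="zyx" flip="1,1,1"/>
    <joint name="{q}h" prox="PL" dist="{c}TH" sequence="zxy" flip="1,1,1"/>
    <joint name="{q}k" prox="{c}TH" dist="{c}SH" sequence="zxy" flip="-1,1,1"/>
    <joint name="{q}a" prox="{c}SH" dist="{c}FT" sequence="zyx" flip="1,1,1"/>
  </chain>
  <orientations tags="PL,{s}SK,{s}FC,{s}FD,{s}HJCK,{s}GTKL,{c}TH,{c}SH,{c}FT"/>
</model>
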