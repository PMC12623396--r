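<?xml version="1.0" encoding="UTF-8"?>
<!-- Transtibial (TT) running-specific prosthesis model definition.
     The socket-clamp and foot-clamp degenerate into a single foot-clamp:
     the J-shaped blade bolts straight to the socket posterior box, so
     there is no prosthetic knee joint in the chain. Placeholders as in
     the TF model. -->
<model name="rsp-tt" level="TT" rpf_shapes="J">
  <markers>
    <marker name="{s}FAP" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}FAD" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}LAP" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}LAD" type="technical" class="permanent" segment="socket"/>
    <marker name="{s}MAD" type="technical" class="static" segment="socket" host="socket"/>
    <!-- J-shape foot-clamp markers on the proximal blade -->
    <marker name="{s}CLPL" type="mechanical" class="permanent" segment="foot_clamp"/>
    <marker name="{s}CLDL" type="mechanical" class="permanent" segment="foot_clamp"/>
    <marker name="{s}CLPM" type="mechanical" class="permanent" segment="foot_clamp"/>
    <marker name="{s}CLDM" type="mechanical" class="permanent" segment="foot_clamp"/>
    <!-- socket-box connection screws, wand-calibrated -->
    <marker name="{s}WP" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <marker name="{s}WD" type="mechanical" class="wand" segment="foot_clamp" host="rpf_proximal"/>
    <!-- technical proximal-RPF cluster; FPA stays on for TT -->
    <marker name="{s}FPA" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FP1" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FP2" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FP3" type="technical" class="permanent" segment="rpf_proximal"/>
    <marker name="{s}FDA" type="technical" class="permanent" segment="rpf_distal"/>
    <marker name="{s}FDM" type="technical" class="permanent" segment="rpf_distal"/>
    <marker name="{s}FDL" type="technical" class="permanent" segment="rpf_distal"/>
    <marker name="RASI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="LASI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="RPSI" type="anatomical" class="permanent" segment="pelvis"/>
    <marker name="LPSI" type="anatomical" class="permanent" segment="pelvis"/>
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
    <frame tag="{s}FC" recipe="foot_clamp_J" inputs="{s}CLPL,{s}CLDL,{s}CLPM,{s}CLDM" side="prosthetic"/>
    <frame tag="{s}FD" recipe="distal_rpf" inputs="{s}FDA,{s}FDM,{s}FDL" side="prosthetic"/>
    <frame tag="{s}FP" recipe="technical_fp" inputs="{s}FP1,{s}FP2,{s}FP3" side="prosthetic"/>
    <frame tag="{c}TH" recipe="thigh" inputs="{c}HJC,{c}LEP,{c}MEP" side="sound"/>
    <frame tag="{c}SH" recipe="shank" inputs="{c}LEP,{c}MEP,{c}LML,{c}MML" side="sound"/>
    <frame tag="{c}FT" recipe="foot" inputs="{c}CAL,{c}MT1,{c}MT5" side="sound"/>
  </frames>
  <chain>
    <joint name="{p}htt" prox="PL" dist="{s}SK" sequence="zxy" flip="1,1,1"/>
    <joint name="{p}att" prox="{s}FC" dist="{s}FD" sequence="zyx" flip="1,1,1"/>
    <joint name="{q}h" prox="PL" dist="{c}TH" sequence="zxy" flip="1,1,1"/>
    <joint name="{q}k" prox="{c}TH" dist="{c}SH" sequence="zxy" flip="-1,1,1"/>
    <joint name="{q}a" prox="{c}SH" dist="{c}FT" sequence="zyx" flip="1,1,1"/>
  </chain>
  <orientations tags="PL,{s}SK,{s}FC,{s}FD,{c}TH,{c}SH,{c}FT"/>
</model>
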