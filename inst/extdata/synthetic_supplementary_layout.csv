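Video;Subject;Input;Method;Rep;FrameNo;PosX;PosY;Time_s
vid01;P1;mouse;fw;1;0;100.5;200.25;0.31
vid01;P1;mouse;fw;1;1;101.75;201.0;0.93
vid01;P1;mouse;fw;1;2;103.0;202.5;1.55
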