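point_id,label,side,anchor_x,anchor_y,anchor_z,dimension
0,nose_tip,mid,0,0,1.5,NA
1,nose_bridge,mid,0,0.035,1.515,NA
2,forehead_center,mid,0,0.085,1.525,NA
3,philtrum,mid,0,-0.02,1.505,NA
4,mouth_center,mid,0,-0.045,1.505,NA
5,chin,mid,0,-0.09,1.515,NA
6,left_brow_inner,left,0.02,0.06,1.52,int
7,left_brow_mid,left,0.045,0.065,1.525,dep
8,left_brow_outer,left,0.07,0.06,1.53,anx
9,left_eye_inner,left,0.018,0.04,1.515,hos
10,left_eye_top,left,0.04,0.045,1.515,pho
11,left_eye_outer,left,0.062,0.04,1.52,psy
12,left_cheek_upper,left,0.055,0.005,1.515,int
13,left_cheek_lower,left,0.05,-0.03,1.515,dep
14,left_nose_wing,left,0.018,-0.005,1.505,anx
15,left_mouth_corner,left,0.028,-0.045,1.51,hos
16,left_lip_upper,left,0.014,-0.035,1.505,pho
17,left_lip_lower,left,0.014,-0.055,1.505,psy
18,left_jaw_upper,left,0.07,-0.02,1.535,int
19,left_jaw_mid,left,0.06,-0.055,1.53,dep
20,left_jaw_lower,left,0.035,-0.085,1.52,anx
21,right_brow_inner,right,-0.02,0.06,1.52,int
22,right_brow_mid,right,-0.045,0.065,1.525,dep
23,right_brow_outer,right,-0.07,0.06,1.53,anx
24,right_eye_inner,right,-0.018,0.04,1.515,hos
25,right_eye_top,right,-0.04,0.045,1.515,pho
26,right_eye_outer,right,-0.062,0.04,1.52,psy
27,right_cheek_upper,right,-0.055,0.005,1.515,int
28,right_cheek_lower,right,-0.05,-0.03,1.515,dep
29,right_nose_wing,right,-0.018,-0.005,1.505,anx
30,right_mouth_corner,right,-0.028,-0.045,1.51,hos
31,right_lip_upper,right,-0.014,-0.035,1.505,pho
32,right_lip_lower,right,-0.014,-0.055,1.505,psy
33,right_jaw_upper,right,-0.07,-0.02,1.535,int
34,right_jaw_mid,right,-0.06,-0.055,1.53,dep
35,right_jaw_lower,right,-0.035,-0.085,1.52,anx
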